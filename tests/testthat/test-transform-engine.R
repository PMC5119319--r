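test_that("decorated calls append events and write numbered audit files", {
  img <- imageFromArray(matrix(c(10L, 60L, 50L, 51L), 2, 2), "t",
                        dtype = "uint8")
  dir <- with_audit_dir({
    out <- threshold_abs(img, 50)
    expect_identical(pixels(out),
                     matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
    expect_identical(events(out), "threshold_abs(image, 50)")
    out2 <- invert(out)
    expect_identical(events(out2),
                     c("threshold_abs(image, 50)", "invert(image)"))
    expect_identical(creation(out2), "t")
  })
  expect_identical(sort(list.files(dir)),
                   sort(c("1_threshold_abs.png", "2_invert.png")))
})

test_that("audit toggle suppresses files but history still grows", {
  img <- imageFromArray(matrix(1L, 3, 3), "x", dtype = "uint8")
  dir <- tempfile()
  dir.create(dir)
  old_d <- auditDirectory(dir)
  on.exit(auditDirectory(old_d))
  out <- no_audit(threshold_abs(img, 0))
  expect_length(events(out), 1L)
  expect_identical(list.files(dir), character(0))
})

test_that("keyword arguments render as name=value and counter resets", {
  m <- matrix(FALSE, 30, 30)
  m[2:21, 2:21] <- TRUE
  img <- imageFromArray(m, "blob")
  dir <- with_audit_dir({
    out <- remove_small_objects(img, min_size = 500)
    expect_identical(events(out),
                     "remove_small_objects(image, min_size=500)")
    expect_identical(auditCounter(), 2L)
    resetAudit()
    expect_identical(auditCounter(), 1L)
  })
  expect_identical(list.files(dir), "1_remove_small_objects.png")
})

test_that("a bare matrix input starts a fresh history", {
  out <- no_audit(threshold_abs(matrix(0:3, 2, 2), 1))
  expect_length(events(out), 1L)
  expect_match(creation(out), "created by threshold_abs")
})

test_that("decorating the identity is a pixel no-op that appends one event", {
  ident <- transformation(function(image) pixels(image), "ident")
  img <- imageFromArray(matrix(1:9, 3, 3), "i")
  out <- no_audit(ident(img))
  expect_identical(pixels(out), pixels(img))
  expect_length(events(out), 1L)
})

test_that("a transform returning a non-image errors", {
  bad <- transformation(function(image) "nope", "bad")
  img <- imageFromArray(matrix(1L, 2, 2), "i")
  expect_error(no_audit(bad(img)), "must return a 2D image")
})

test_that("threshold_abs is strict and handles extreme cutoffs", {
  img <- imageFromArray(matrix(c(10L, 60L, 50L, 51L), 2, 2), "t")
  no_audit({
    expect_identical(pixels(threshold_abs(img, 50)),
                     matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
    expect_true(all(pixels(threshold_abs(img, 9))))
    expect_false(any(pixels(threshold_abs(img, 60))))
  })
})

test_that("invert is an involution and conserves pixel counts", {
  set.seed(21)
  no_audit({
    for (rep in 1:10) {
      m <- random_mask(9, 7)
      img <- imageFromArray(m, "m")
      inv <- invert(img)
      expect_identical(pixels(invert(inv)), m)
      expect_identical(sum(m) + sum(pixels(inv)), length(m))
    }
    expect_error(invert(imageFromArray(matrix(1L, 2, 2), "int")), "boolean")
  })
})

test_that("dilate/erode use the 3x3 cross with FALSE border padding", {
  no_audit({
    m <- matrix(FALSE, 5, 5)
    m[3, 3] <- TRUE
    d <- pixels(dilate_binary(imageFromArray(m, "pt")))
    want <- matrix(FALSE, 5, 5)
    want[3, 2:4] <- TRUE
    want[2:4, 3] <- TRUE
    expect_identical(d, want)

    all_false <- imageFromArray(matrix(FALSE, 4, 4), "f")
    expect_false(any(pixels(dilate_binary(all_false))))
    expect_false(any(pixels(erode_binary(all_false))))

    solid <- imageFromArray(matrix(TRUE, 3, 3), "s")
    er <- pixels(erode_binary(solid))
    expect_identical(which(er), 5L)  # centre only survives

    # extensivity / anti-extensivity over random masks
    set.seed(5)
    for (rep in 1:15) {
      msk <- random_mask(8, 8)
      img <- imageFromArray(msk, "r")
      expect_true(all(msk[!pixels(dilate_binary(img))] == FALSE))
      expect_true(all(pixels(dilate_binary(img))[msk]))   # result >= input
      expect_true(all(msk[pixels(erode_binary(img))]))    # result <= input
    }
    # erode(dilate(singleton)) contains the singleton
    pt <- matrix(FALSE, 7, 7)
    pt[4, 4] <- TRUE
    ed <- pixels(erode_binary(dilate_binary(imageFromArray(pt, "pt"))))
    expect_true(ed[4, 4])
  })
})

test_that("remove_small_objects keeps components at exactly min_size", {
  no_audit({
    m <- matrix(FALSE, 30, 40)
    m[2:21, 2:26] <- TRUE            # 20 x 25 = 500 pixels
    kept <- pixels(remove_small_objects(imageFromArray(m, "b"),
                                        min_size = 500))
    expect_identical(kept, m)

    m2 <- m
    m2[2, 2] <- FALSE                # 499 pixels
    gone <- pixels(remove_small_objects(imageFromArray(m2, "b"),
                                        min_size = 500))
    expect_false(any(gone))

    # min_size = 1 is the identity
    set.seed(3)
    r <- random_mask(10, 10)
    expect_identical(pixels(remove_small_objects(imageFromArray(r, "r"),
                                                 min_size = 1)), r)

    # two blobs, areas 3 and 10, threshold 5
    two <- matrix(FALSE, 10, 10)
    two[1, 1:3] <- TRUE
    two[6:7, 2:6] <- TRUE
    out <- pixels(remove_small_objects(imageFromArray(two, "t"),
                                       min_size = 5))
    expect_identical(sum(out), 10L)
    expect_false(any(out[1, ]))
  })
})

test_that("binary transforms preserve shape and dtype", {
  no_audit({
    img <- imageFromArray(random_mask(6, 9), "m")
    for (f in list(invert, dilate_binary, erode_binary)) {
      out <- f(img)
      expect_identical(dim(out), c(6L, 9L))
      expect_identical(dtype(out), "logical")
    }
  })
})
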