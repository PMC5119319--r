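test_that("connected_components labels separated groups in raster order", {
  no_audit({
    m <- matrix(c(1L, 0L, 0L,
                  1L, 0L, 1L,
                  0L, 0L, 1L), 3, 3, byrow = TRUE)
    seg <- connected_components(imageFromArray(m, "m"), background = 0)
    expect_identical(identifiers(seg), c(1L, 2L))
    expect_identical(labels2d(seg)[1, 1], 1L)     # raster-first component
    expect_identical(labels2d(seg)[2, 3], 2L)

    none <- connected_components(imageFromArray(matrix(0L, 3, 3), "z"),
                                 background = 0)
    expect_identical(identifiers(none), integer(0))
  })
})

test_that("connected_components matches a brute-force flood fill", {
  no_audit({
    set.seed(101)
    for (rep in 1:100) {
      m <- matrix(as.integer(runif(256) < 0.45), 16, 16)
      seg <- connected_components(imageFromArray(m, "r"), background = 0)
      expect_identical(labels2d(seg), oracle_flood_fill(m, 0L))
    }
  })
})

test_that("connected_components is idempotent under relabelling", {
  no_audit({
    set.seed(7)
    for (rep in 1:10) {
      m <- matrix(as.integer(runif(144) < 0.4), 12, 12)
      seg1 <- connected_components(imageFromArray(m, "r"), background = 0)
      seg2 <- connected_components(seg1, background = 0)
      expect_identical(labels2d(seg2), labels2d(seg1))
    }
  })
})

test_that("fresh component labels are consecutive 1..K", {
  no_audit({
    set.seed(13)
    m <- matrix(as.integer(runif(400) < 0.3), 20, 20)
    seg <- connected_components(imageFromArray(m, "r"), background = 0)
    k <- length(identifiers(seg))
    expect_identical(identifiers(seg), seq_len(k))
  })
})

test_that("watershed on flat terrain matches the nearest-seed oracle", {
  no_audit({
    land <- matrix(0, 11, 13)
    seeds <- matrix(0L, 11, 13)
    seeds[3, 3] <- 1L
    seeds[9, 11] <- 2L
    seg <- watershed_with_seeds(land, seeds = SegmentedImage(seeds))
    want <- oracle_nearest_seed(seeds)
    got <- labels2d(seg)
    idx <- !is.na(want)
    expect_identical(got[idx], want[idx])
    # equidistant pixels are deterministic across runs
    seg2 <- watershed_with_seeds(land, seeds = SegmentedImage(seeds))
    expect_identical(labels2d(seg2), got)

    set.seed(33)
    for (rep in 1:10) {
      s <- matrix(0L, 9, 9)
      pts <- sample.int(81L, 3L)
      s[pts] <- 1:3
      w <- labels2d(watershed_with_seeds(matrix(0, 9, 9),
                                         seeds = SegmentedImage(s)))
      o <- oracle_nearest_seed(s)
      expect_identical(w[!is.na(o)], o[!is.na(o)])
    }
  })
})

test_that("watershed labels every unmasked pixel with a seed label", {
  no_audit({
    s <- matrix(0L, 6, 6)
    s[3, 3] <- 5L
    seg <- watershed_with_seeds(matrix(runif(36), 6, 6),
                                seeds = SegmentedImage(s))
    expect_true(all(labels2d(seg) == 5L))

    mask <- matrix(TRUE, 6, 6)
    mask[1, ] <- FALSE
    segm <- watershed_with_seeds(matrix(runif(36), 6, 6),
                                 seeds = SegmentedImage(s), mask = mask)
    expect_true(all(labels2d(segm)[1, ] == 0L))
    expect_true(all(labels2d(segm)[-1, ] == 5L))
  })
})

test_that("watershed validates its inputs", {
  no_audit({
    s <- SegmentedImage(matrix(0L, 3, 3))
    expect_error(watershed_with_seeds(matrix(0, 3, 3), seeds = s),
                 "at least one")
    s2 <- SegmentedImage(matrix(1L, 4, 4))
    expect_error(watershed_with_seeds(matrix(0, 3, 3), seeds = s2), "shape")
    expect_error(watershed_with_seeds(matrix(0, 3, 3), seeds = matrix(1L, 3, 3)),
                 "SegmentedImage")
  })
})

test_that("identifiers, region extraction and removal are consistent", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1:2] <- 3L
  lab[4, 3:4] <- 7L
  seg <- SegmentedImage(lab)
  expect_identical(identifiers(seg), c(3L, 7L))

  r3 <- regionByIdentifier(seg, 3)
  expect_identical(area(r3), 2L)
  expect_identical(pixels(r3), lab == 3L)
  expect_error(regionByIdentifier(seg, 4), "no segment")

  total <- sum(labels2d(seg) > 0L)
  seg <- removeRegion(seg, 3)
  expect_identical(identifiers(seg), 7L)
  expect_identical(sum(labels2d(seg) > 0L), total - 2L)
  expect_error(removeRegion(seg, 3), "no segment")
  seg <- removeRegion(seg, 7)
  expect_identical(identifiers(seg), integer(0))
  expect_true(all(labels2d(seg) == 0L))
})

test_that("regions partition the labelled pixels", {
  no_audit({
    set.seed(44)
    m <- matrix(as.integer(runif(225) < 0.4), 15, 15)
    seg <- connected_components(imageFromArray(m, "p"), background = 0)
    ids <- identifiers(seg)
    acc <- matrix(0L, 15, 15)
    for (i in ids) acc <- acc + pixels(regionByIdentifier(seg, i))
    expect_true(all(acc <= 1L))                      # pairwise disjoint
    expect_identical(acc == 1L, labels2d(seg) > 0L)  # union = foreground
  })
})
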