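test_that("inner, border and perimeter of a solid square", {
  sq <- Region(matrix(TRUE, 3, 3))
  expect_identical(which(pixels(inner(sq))), 5L)        # centre pixel
  expect_identical(area(border(sq)), 8L)
  expect_identical(perimeter(sq), 8L)
  expect_identical(area(sq), 9L)

  single <- matrix(FALSE, 3, 3)
  single[2, 2] <- TRUE
  s <- Region(single)
  expect_identical(area(inner(s)), 0L)
  expect_identical(perimeter(s), 1L)
})

test_that("region morphology satisfies partition/extensivity properties", {
  set.seed(9)
  for (rep in 1:25) {
    r <- Region(random_mask(10, 12))
    m <- pixels(r)
    inn <- pixels(inner(r))
    bor <- pixels(border(r))
    expect_true(all(m[inn]))                      # inner subset of mask
    expect_false(any(inn & bor))                  # disjoint
    expect_identical(inn | bor, m)                # partition of the mask
    expect_identical(area(inner(r)) + area(border(r)), area(r))
    expect_lte(perimeter(r), area(r))
    expect_true(all(pixels(dilate(r))[m]))        # dilation extensive
    hull <- pixels(convexHull(r))
    expect_true(all(hull[m]))                     # hull contains mask
  }
  empty <- Region(matrix(FALSE, 4, 4))
  expect_identical(area(dilate(empty)), 0L)
  expect_identical(area(convexHull(empty)), 0L)
})

test_that("convex hull: fixed point, L-tromino fill, idempotence", {
  rect <- matrix(FALSE, 6, 7)
  rect[2:4, 3:6] <- TRUE
  r <- Region(rect)
  expect_identical(pixels(convexHull(r)), rect)

  # L-shaped tromino fills to the 2x2 square (pixel-square hull)
  ltro <- matrix(FALSE, 4, 4)
  ltro[2, 2] <- TRUE
  ltro[2, 3] <- TRUE
  ltro[3, 2] <- TRUE
  want <- ltro
  want[3, 3] <- TRUE
  expect_identical(pixels(convexHull(Region(ltro))), want)

  # brute-force half-plane cross-check on a random small mask
  set.seed(15)
  msk <- random_mask(7, 7, density = 0.25)
  msk[4, 4] <- TRUE
  h1 <- pixels(convexHull(Region(msk)))
  h2 <- pixels(convexHull(convexHull(Region(msk))))
  expect_identical(h1, h2)                        # idempotent
})

test_that("centroid averages member coordinates", {
  m <- matrix(FALSE, 5, 6)
  m[3, 4] <- TRUE
  expect_identical(unname(centroid(Region(m))), c(3, 4))

  blk <- matrix(FALSE, 4, 4)
  blk[1:2, 1:2] <- TRUE
  expect_identical(unname(centroid(Region(blk))), c(1.5, 1.5))

  # symmetric mask: centroid lies on the symmetry axis
  sym <- matrix(FALSE, 5, 5)
  sym[2:4, 3] <- TRUE
  sym[3, 2:4] <- TRUE
  expect_identical(unname(centroid(Region(sym))), c(3, 3))
})

test_that("false-colour encoding is deterministic with black background", {
  lab <- matrix(0L, 4, 4)
  lab[1, 1:2] <- 1L
  lab[3, 3] <- 2L
  seg <- SegmentedImage(lab)
  b1 <- falseColourPng(seg)
  b2 <- falseColourPng(seg)
  expect_identical(b1, b2)
  rgb <- decodePng(b1)
  expect_identical(dim(rgb), c(4L, 4L, 3L))
  expect_identical(rgb[4, 4, ], c(0L, 0L, 0L))    # background black
  cols <- unique(matrix(rgb, ncol = 3L))
  expect_identical(nrow(cols), 3L)                # bg + two segment colours
  expect_identical(unname(rgb[1, 1, ]),
                   unname(pretty_color_from_identifier(1)))
  # all-background image is all black
  black <- decodePng(falseColourPng(SegmentedImage(matrix(0L, 3, 3))))
  expect_true(all(black == 0L))
})

test_that("pretty colours follow the pinned LCG recipe", {
  # golden values computed once from the pinned recurrence
  # x_{n+1} = (1664525 x_n + 1013904223) mod 2^32, channel = x mod 193 + 63
  expect_identical(unname(pretty_color_from_identifier(1)),
                   c(109L, 238L, 114L))
  expect_identical(unname(pretty_color_from_identifier(2)),
                   c(202L, 215L, 164L))
  expect_identical(unname(pretty_color_from_identifier(7)),
                   c(88L, 100L, 244L))
  expect_identical(pretty_color_from_identifier(7),
                   pretty_color_from_identifier(7))
  for (i in c(1L, 5L, 99L, 12345L)) {
    col <- pretty_color_from_identifier(i)
    expect_true(all(col >= 63L & col <= 255L))
  }
  expect_error(pretty_color_from_identifier(0), "positive")
})
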