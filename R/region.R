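#' @include segmentation.R
NULL

#' Boolean mask of one segment
#'
#' A Region is a 2D boolean mask (TRUE = member pixel). All derived
#' morphology -- \code{\link{area}}, \code{\link{perimeter}},
#' \code{\link{inner}}, \code{\link{border}}, \code{\link{convexHull}},
#' \code{\link{centroid}}, \code{\link{dilate}} -- are pure functions of the
#' mask. \code{inner(x)} is a subset of the mask, \code{border(x)} is
#' \code{mask AND NOT inner}, and \code{convexHull(x)} contains the mask.
#'
#' @slot mask logical matrix.
#' @export
setClass("Region", representation(mask = "matrix"))

setValidity("Region", function(object) {
  if (!is.logical(object@mask)) return("mask must be a logical matrix")
  if (length(dim(object@mask)) != 2L) return("mask must be 2D")
  TRUE
})

#' Construct a Region from a boolean mask
#'
#' @param mask logical matrix (TRUE = member pixel).
#' @return A \linkS4class{Region}.
#' @examples
#' r <- Region(matrix(TRUE, 3, 3))
#' area(r); perimeter(r); centroid(r)
#' @export
Region <- function(mask) {
  if (!is.logical(mask)) stop("mask must be logical", call. = FALSE)
  new("Region", mask = mask)
}

#' @rdname pixels
#' @export
setMethod("pixels", "Region", function(x) x@mask)

setMethod("dim", "Region", function(x) dim(x@mask))

setMethod("show", "Region", function(object) {
  cat(sprintf("Region %dx%d, area %d\n", nrow(object@mask),
              ncol(object@mask), sum(object@mask)))
  invisible(NULL)
})

#' @rdname area
#' @export
setMethod("area", "Region", function(x) sum(x@mask))

#' @rdname inner
#' @export
setMethod("inner", "Region", function(x) Region(.erode_cross(x@mask)))

#' @rdname border
#' @export
setMethod("border", "Region", function(x) {
  Region(x@mask & !.erode_cross(x@mask))
})

#' @rdname perimeter
#' @export
setMethod("perimeter", "Region", function(x) {
  sum(x@mask & !.erode_cross(x@mask))
})

#' @rdname dilate
#' @export
setMethod("dilate", "Region", function(x) Region(.dilate_cross(x@mask)))

#' @rdname centroid
#' @export
setMethod("centroid", "Region", function(x) {
  idx <- which(x@mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
})

#' @rdname convexHull
#' @export
setMethod("convexHull", "Region", function(x) {
  m <- x@mask
  if (sum(m) == 0L) return(Region(m))
  # discrete convex closure: iterate the rasterised hull to its fixed point,
  # so convexHull(convexHull(x)) == convexHull(x) holds exactly
  repeat {
    h <- .hull_once(m)
    if (identical(h, m)) return(Region(h))
    m <- h
  }
})

# one rasterisation pass: hull polygon over the member pixels' unit-square
# corners; a pixel joins when its centre lies inside or on the polygon
.hull_once <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  # hull over the unit squares of the member pixels: each pixel contributes
  # its four corners (centre +- 0.5 in each axis)
  pr <- c(idx[, 1] - 0.5, idx[, 1] - 0.5, idx[, 1] + 0.5, idx[, 1] + 0.5)
  pc <- c(idx[, 2] - 0.5, idx[, 2] + 0.5, idx[, 2] - 0.5, idx[, 2] + 0.5)
  h <- grDevices::chull(pc, pr)           # vertex indices, clockwise in (x, y)
  vr <- pr[h]
  vc <- pc[h]
  k <- length(h)
  # half-plane test: a pixel centre belongs when it is on the inner side of
  # (or on) every hull edge; tolerance absorbs floating-point noise
  eps <- 1e-9
  cand_r <- rep(seq_len(nrow(m)), times = ncol(m))
  cand_c <- rep(seq_len(ncol(m)), each = nrow(m))
  ok <- rep(TRUE, length(cand_r))
  for (e in seq_len(k)) {
    r1 <- vr[e]; c1 <- vc[e]
    r2 <- vr[e %% k + 1L]; c2 <- vc[e %% k + 1L]
    # chull(x=c, y=r) returns vertices clockwise in (c, r) space; for a
    # clockwise polygon interior points give non-positive cross products
    cross <- (c2 - c1) * (cand_r - r1) - (r2 - r1) * (cand_c - c1)
    ok <- ok & (cross >= -eps)
  }
  # orientation can flip for degenerate hulls; accept the orientation that
  # contains the original mask
  hull <- matrix(ok, nrow = nrow(m))
  if (!all(hull[m])) {
    ok <- rep(TRUE, length(cand_r))
    for (e in seq_len(k)) {
      r1 <- vr[e]; c1 <- vc[e]
      r2 <- vr[e %% k + 1L]; c2 <- vc[e %% k + 1L]
      cross <- (c2 - c1) * (cand_r - r1) - (r2 - r1) * (cand_c - c1)
      ok <- ok & (cross <= eps)
    }
    hull <- matrix(ok, nrow = nrow(m))
  }
  hull
}
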