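#' @include audit.R
NULL

# extract a plain matrix from ProvImage / SegmentedImage / matrix input
.pixels_of <- function(x) {
  if (is(x, "ProvImage")) x@pixels
  else if (is(x, "SegmentedImage")) x@labels
  else if (is.matrix(x)) x
  else stop("expected an image or 2D matrix", call. = FALSE)
}

.binary_of <- function(x) {
  m <- .pixels_of(x)
  if (!is.logical(m)) stop("expected a boolean image", call. = FALSE)
  m
}

# shift a logical matrix by (dr, dc), padding FALSE at the borders
.shift_false <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr
  cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# 3x3 cross structuring element, shared by all morphology in the package
.dilate_cross <- function(m) {
  m | .shift_false(m, 1L, 0L) | .shift_false(m, -1L, 0L) |
      .shift_false(m, 0L, 1L) | .shift_false(m, 0L, -1L)
}

.erode_cross <- function(m) {
  m & .shift_false(m, 1L, 0L) & .shift_false(m, -1L, 0L) &
      .shift_false(m, 0L, 1L) & .shift_false(m, 0L, -1L)
}

#' Built-in audited binary transforms
#'
#' The transforms used by the seeded-watershed demo pipeline. All are
#' decorated with \code{\link{transformation}}: each call appends a history
#' event and (when auditing is enabled) writes a numbered PNG snapshot.
#' All are shape- and dtype-preserving on their boolean inputs.
#'
#' \describe{
#'   \item{\code{threshold_abs(image, cutoff)}}{boolean image, TRUE exactly
#'     where pixel > cutoff (strict).}
#'   \item{\code{invert(image)}}{elementwise logical negation.}
#'   \item{\code{dilate_binary(image)} / \code{erode_binary(image)}}{
#'     morphological dilation/erosion with a 3x3 cross (4-connected)
#'     structuring element; borders behave as if padded FALSE.}
#'   \item{\code{remove_small_objects(image, min_size)}}{8-connected TRUE
#'     components with area < min_size are set FALSE; components with area
#'     >= min_size are retained.}
#' }
#'
#' @param image a boolean \linkS4class{ProvImage} (or bare logical matrix);
#'   \code{threshold_abs} accepts any numeric image.
#' @param cutoff finite numeric threshold (strictly exceeded pixels map TRUE).
#' @param min_size positive integer; smallest retained component area.
#' @return A boolean \linkS4class{ProvImage} with one appended history event.
#' @examples
#' old <- auditEnabled(FALSE)
#' img <- imageFromArray(matrix(c(10L, 60L, 50L, 51L), 2, 2), "demo")
#' pixels(threshold_abs(img, 50))
#' auditEnabled(old)
#' @name transforms
NULL

#' @rdname transforms
#' @export
threshold_abs <- transformation(function(image, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, is.finite(cutoff))
  .pixels_of(image) > cutoff
}, "threshold_abs")

#' @rdname transforms
#' @export
invert <- transformation(function(image) {
  !.binary_of(image)
}, "invert")

#' @rdname transforms
#' @export
dilate_binary <- transformation(function(image) {
  .dilate_cross(.binary_of(image))
}, "dilate_binary")

#' @rdname transforms
#' @export
erode_binary <- transformation(function(image) {
  .erode_cross(.binary_of(image))
}, "erode_binary")

#' @rdname transforms
#' @export
remove_small_objects <- transformation(function(image, min_size) {
  stopifnot(is.numeric(min_size), length(min_size) == 1L, min_size >= 1)
  m <- .binary_of(image)
  lab <- .cc_label(matrix(as.integer(m), nrow = nrow(m)), 0L)
  k <- max(lab)
  if (k == 0L) return(m)
  areas <- tabulate(lab, nbins = k)
  keep <- which(areas >= min_size)
  matrix(lab %in% keep, nrow = nrow(m))
}, "remove_small_objects")
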