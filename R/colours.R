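#' @include region.R
NULL

#' Deterministic "pretty" colour for a segment identifier
#'
#' Colours are derived from a linear congruential generator pinned to fixed
#' constants (modulus 2^32, multiplier 1664525, increment 1013904223 --
#' Numerical Recipes), seeded with the identifier: three successive draws
#' give the red, green and blue channels, each mapped into [63, 255] via
#' \code{v mod 193 + 63} so segments stay visible on a black background. No
#' platform RNG is involved: the same identifier yields the same colour
#' everywhere, forever.
#'
#' @param i positive integer segment identifier.
#' @return Named integer vector \code{c(r, g, b)}, each channel in [63, 255].
#' @examples
#' pretty_color_from_identifier(1)
#' @export
pretty_color_from_identifier <- function(i) {
  if (length(i) != 1L || !is.numeric(i) || is.na(i) || i < 1 || i != round(i))
    stop("identifier must be a single positive integer", call. = FALSE)
  m <- 2^32
  a <- 1664525
  inc <- 1013904223
  x <- as.double(i) %% m
  ch <- integer(3)
  for (k in 1:3) {
    x <- (a * x + inc) %% m       # exact: a * x < 2^53
    ch[k] <- as.integer(x %% 193 + 63)
  }
  names(ch) <- c("r", "g", "b")
  ch
}

.check_color <- function(color) {
  color <- as.integer(color)
  if (length(color) != 3L || any(is.na(color)) || any(color < 0L) ||
      any(color > 255L))
    stop("color must be three integers in [0, 255]", call. = FALSE)
  color
}

# label matrix -> integer h x w x 3 canvas, background black
.false_colour_canvas <- function(labels) {
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0L]
  lut_r <- integer(length(ids))
  lut_g <- integer(length(ids))
  lut_b <- integer(length(ids))
  for (k in seq_along(ids)) {
    col <- pretty_color_from_identifier(ids[k])
    lut_r[k] <- col[1]
    lut_g[k] <- col[2]
    lut_b[k] <- col[3]
  }
  pos <- match(as.vector(labels), ids)          # NA for background
  take <- function(lut) {
    v <- ifelse(is.na(pos), 0L, lut[pos])
    matrix(v, nrow = nrow(labels))
  }
  out <- array(0L, dim = c(nrow(labels), ncol(labels), 3L))
  out[, , 1] <- take(lut_r)
  out[, , 2] <- take(lut_g)
  out[, , 3] <- take(lut_b)
  out
}

#' @rdname falseColourPng
#' @export
setMethod("falseColourPng", "SegmentedImage", function(x) {
  png::writePNG(.false_colour_canvas(x@labels) / 255, target = raw())
})
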