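#' @include colours.R font.R
NULL

#' RGB annotation canvas
#'
#' An 8-bit RGB canvas over a grayscale background image. All drawing
#' operations clip silently to the canvas bounds rather than error, and touch
#' only the pixels their contract names. R value semantics apply: drawing
#' functions return the modified canvas.
#'
#' @slot canvas integer array \code{h x w x 3} of values in [0, 255].
#' @export
setClass("AnnotatedImage", representation(canvas = "array"))

setValidity("AnnotatedImage", function(object) {
  d <- dim(object@canvas)
  if (length(d) != 3L || d[3] != 3L)
    return("canvas must be an h x w x 3 array")
  if (!is.integer(object@canvas)) return("canvas must hold integers")
  if (any(object@canvas < 0L | object@canvas > 255L))
    return("canvas values must lie in [0, 255]")
  TRUE
})

#' Create an annotation canvas from a grayscale image
#'
#' The input is min-max rescaled to [0, 255] (a constant image maps to 0,
#' i.e. a black canvas) and copied into all three channels.
#'
#' @param image a \linkS4class{ProvImage} or numeric/logical matrix.
#' @return An \linkS4class{AnnotatedImage} of the same spatial shape.
#' @examples
#' canvas <- fromGrayscale(matrix(0:255, 16, 16))
#' @export
fromGrayscale <- function(image) {
  m <- .pixels_of(image)
  if (is.logical(m)) m <- matrix(as.integer(m), nrow = nrow(m))
  lo <- min(m)
  hi <- max(m)
  g <- if (hi == lo) matrix(0L, nrow(m), ncol(m))
       else matrix(as.integer(floor((m - lo) / (hi - lo) * 255 + 0.5)),
                   nrow = nrow(m))
  canvas <- array(0L, dim = c(nrow(m), ncol(m), 3L))
  canvas[, , 1] <- g
  canvas[, , 2] <- g
  canvas[, , 3] <- g
  new("AnnotatedImage", canvas = canvas)
}

#' @rdname pixels
#' @export
setMethod("pixels", "AnnotatedImage", function(x) x@canvas)

setMethod("dim", "AnnotatedImage", function(x) dim(x@canvas))

setMethod("show", "AnnotatedImage", function(object) {
  d <- dim(object@canvas)
  cat(sprintf("AnnotatedImage %dx%d RGB canvas\n", d[1], d[2]))
  invisible(NULL)
})

#' Paint a region onto an annotation canvas
#'
#' Pixels where the region mask is TRUE are set to \code{color} exactly; all
#' other pixels are untouched.
#'
#' @param canvas an \linkS4class{AnnotatedImage}.
#' @param region a \linkS4class{Region} with the same spatial shape.
#' @param color integer vector \code{c(r, g, b)} in [0, 255].
#' @return The modified canvas.
#' @export
maskRegion <- function(canvas, region, color) {
  stopifnot(is(canvas, "AnnotatedImage"), is(region, "Region"))
  color <- .check_color(color)
  m <- region@mask
  if (!identical(dim(m), dim(canvas@canvas)[1:2]))
    stop("region shape does not match canvas", call. = FALSE)
  for (ch in 1:3) {
    plane <- canvas@canvas[, , ch]
    plane[m] <- color[ch]
    canvas@canvas[, , ch] <- plane
  }
  canvas
}

# set one pixel, clipping silently
.put_pixel <- function(canvas, r, c, color) {
  d <- dim(canvas@canvas)
  if (r < 1L || r > d[1] || c < 1L || c > d[2]) return(canvas)
  canvas@canvas[r, c, ] <- color
  canvas
}

#' Draw a plus-shaped cross on an annotation canvas
#'
#' The cross has arms of length \code{radius} in the four cardinal
#' directions (4 * radius + 1 pixels when unclipped) centred at
#' \code{position}; pixels outside the canvas are clipped silently.
#'
#' @param canvas an \linkS4class{AnnotatedImage}.
#' @param position numeric \code{c(row, col)}, 1-based; fractional positions
#'   are floored.
#' @param color integer vector \code{c(r, g, b)} in [0, 255].
#' @param radius positive integer arm length (default 2).
#' @return The modified canvas.
#' @export
drawCross <- function(canvas, position, color, radius = 2L) {
  stopifnot(is(canvas, "AnnotatedImage"), length(position) == 2L,
            radius >= 1, radius == round(radius))
  color <- .check_color(color)
  r0 <- as.integer(floor(position[1]))
  c0 <- as.integer(floor(position[2]))
  canvas <- .put_pixel(canvas, r0, c0, color)
  for (k in seq_len(radius)) {
    canvas <- .put_pixel(canvas, r0 - k, c0, color)
    canvas <- .put_pixel(canvas, r0 + k, c0, color)
    canvas <- .put_pixel(canvas, r0, c0 - k, color)
    canvas <- .put_pixel(canvas, r0, c0 + k, color)
  }
  canvas
}

#' Write text on an annotation canvas
#'
#' Text is drawn with the embedded 5x7 bitmap font (digits, A-Z, lowercase as
#' uppercase, space) with a 1-pixel inter-glyph gap; unsupported characters
#' are replaced by a hollow box glyph with a warning. With
#' \code{center = TRUE} the text bounding box is centred on \code{position}
#' (offsets rounded toward negative infinity); otherwise the bounding-box
#' top-left corner is anchored at \code{position}. Drawing clips silently at
#' the canvas edges.
#'
#' @param canvas an \linkS4class{AnnotatedImage}.
#' @param text character string to draw.
#' @param position numeric \code{c(row, col)}, 1-based.
#' @param color integer vector \code{c(r, g, b)} in [0, 255]; default white.
#' @param center logical; centre the bounding box on \code{position}.
#' @return The modified canvas.
#' @export
textAt <- function(canvas, text, position, color = c(255L, 255L, 255L),
                   center = FALSE) {
  stopifnot(is(canvas, "AnnotatedImage"), is.character(text),
            length(text) == 1L, length(position) == 2L)
  color <- .check_color(color)
  chars <- strsplit(text, "")[[1]]
  if (length(chars) == 0L) return(canvas)
  box_w <- 6L * length(chars) - 1L
  box_h <- 7L
  if (isTRUE(center)) {
    top <- as.integer(floor(position[1] - (box_h - 1) / 2))
    left <- as.integer(floor(position[2] - (box_w - 1) / 2))
  } else {
    top <- as.integer(floor(position[1]))
    left <- as.integer(floor(position[2]))
  }
  d <- dim(canvas@canvas)
  for (k in seq_along(chars)) {
    g <- .glyph_matrix(chars[k])
    gl <- left + (k - 1L) * 6L
    on <- which(g, arr.ind = TRUE)
    for (j in seq_len(nrow(on))) {
      r <- top + on[j, 1] - 1L
      c <- gl + on[j, 2] - 1L
      if (r >= 1L && r <= d[1] && c >= 1L && c <= d[2])
        canvas@canvas[r, c, ] <- color
    }
  }
  canvas
}

#' Encode an annotation canvas as PNG bytes
#'
#' @param canvas an \linkS4class{AnnotatedImage}.
#' @return Raw vector holding an 8-bit RGB PNG byte stream; decoding and
#'   re-encoding is the identity.
#' @export
annotationPng <- function(canvas) {
  stopifnot(is(canvas, "AnnotatedImage"))
  png::writePNG(canvas@canvas / 255, target = raw())
}
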