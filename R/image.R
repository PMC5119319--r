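#' @include history.R
NULL

.DTYPES <- c("logical", "uint8", "uint16", "integer", "double")

#' Provenance-carrying 2D image
#'
#' A 2D array of pixel intensities together with the history of how it was
#' produced. The stored value type (\code{dtype}) is preserved through
#' construction -- no silent rescaling of stored pixels. Coordinates are
#' (row, col), 1-based, throughout the package.
#'
#' @slot pixels matrix of pixel values. Storage mode is \code{logical} for
#'   dtype \code{"logical"}, \code{integer} for \code{"uint8"},
#'   \code{"uint16"} and \code{"integer"}, \code{double} for \code{"double"}.
#' @slot dtype one of \code{"logical"}, \code{"uint8"}, \code{"uint16"},
#'   \code{"integer"}, \code{"double"}.
#' @slot history the \linkS4class{ImageHistory}.
#' @export
setClass("ProvImage",
  representation(pixels = "matrix", dtype = "character",
                 history = "ImageHistory"))

setValidity("ProvImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 2L || nrow(p) < 1L || ncol(p) < 1L)
    return("pixels must be a 2D matrix with positive extents")
  d <- object@dtype
  if (length(d) != 1L || !(d %in% .DTYPES))
    return(sprintf("dtype must be one of %s", paste(.DTYPES, collapse = ", ")))
  mode_ok <- switch(d,
    logical = is.logical(p),
    uint8   = is.integer(p),
    uint16  = is.integer(p),
    integer = is.integer(p),
    double  = is.double(p))
  if (!mode_ok)
    return(sprintf("storage mode %s does not match dtype %s", typeof(p), d))
  if (d == "uint8" && any(p < 0L | p > 255L, na.rm = TRUE))
    return("uint8 pixels must lie in [0, 255]")
  if (d == "uint16" && any(p < 0L | p > 65535L, na.rm = TRUE))
    return("uint16 pixels must lie in [0, 65535]")
  TRUE
})

.infer_dtype <- function(values) {
  if (is.logical(values)) "logical"
  else if (is.integer(values)) "integer"
  else if (is.double(values)) "double"
  else stop("unsupported dtype: ", typeof(values), call. = FALSE)
}

#' Create a ProvImage from a 2D array
#'
#' @param values 2D matrix of logical, integer or double pixel values.
#' @param creationNote text recorded as the history's creation record.
#' @param dtype optional explicit dtype. \code{"uint8"} / \code{"uint16"}
#'   require integer storage within range; by default the dtype is inferred
#'   from the storage mode (\code{logical}, \code{integer} or \code{double}).
#' @return A \linkS4class{ProvImage} sharing \code{values}, with an empty
#'   event list.
#' @examples
#' img <- imageFromArray(matrix(0L, 2, 2), "synthetic 2x2 zeros")
#' events(img)
#' @export
imageFromArray <- function(values, creationNote, dtype = NULL) {
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("values must be a 2D array", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("values must have positive extents", call. = FALSE)
  if (is.null(dtype)) {
    dtype <- .infer_dtype(values)
  } else {
    dtype <- match.arg(dtype, .DTYPES)
    if (dtype %in% c("uint8", "uint16", "integer") && is.double(values) &&
        all(values == round(values)))
      storage.mode(values) <- "integer"
  }
  new("ProvImage", pixels = values, dtype = dtype,
      history = ImageHistory(creationNote))
}

#' Read a grayscale TIFF or PNG file as a ProvImage
#'
#' The creation record contains the absolute path of the file. 8-bit files
#' load as dtype \code{"uint8"}, 16-bit TIFFs as \code{"uint16"}. Multi-page
#' TIFFs and RGB images are rejected.
#'
#' @param path path to a readable single-image grayscale TIFF or PNG file.
#' @return A \linkS4class{ProvImage}.
#' @export
imageFromFile <- function(path) {
  if (!file.exists(path) || dir.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  abs <- normalizePath(path, winslash = "/")
  lower <- tolower(path)
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (length(pages) != 1L)
      stop("multi-page TIFF not supported: ", path, call. = FALSE)
    m <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(m)) != 2L)
      stop("RGB/multi-channel image not supported: ", path, call. = FALSE)
    bps <- attr(m, "bits.per.sample")
    dt <- if (!is.null(bps) && bps == 16L) "uint16" else "uint8"
    m <- matrix(as.integer(m), nrow = nrow(m))
  } else if (grepl("\\.png$", lower)) {
    m <- png::readPNG(path)
    if (length(dim(m)) != 2L)
      stop("RGB/multi-channel image not supported: ", path, call. = FALSE)
    m <- matrix(as.integer(round(m * 255)), nrow = nrow(m))
    dt <- "uint8"
  } else {
    stop("unsupported image format (expected .tif/.tiff/.png): ", path,
         call. = FALSE)
  }
  new("ProvImage", pixels = m, dtype = dt,
      history = ImageHistory(paste0("Created image from ", abs)))
}

#' @rdname pixels
#' @export
setMethod("pixels", "ProvImage", function(x) x@pixels)

#' @rdname provenance
#' @export
setMethod("provenance", "ProvImage", function(x) x@history)

#' @rdname creation
#' @export
setMethod("creation", "ProvImage", function(x) x@history@creation)

#' @rdname events
#' @export
setMethod("events", "ProvImage", function(x) x@history@events)

#' @rdname dtype
#' @export
setMethod("dtype", "ProvImage", function(x) x@dtype)

setMethod("dim", "ProvImage", function(x) dim(x@pixels))

setMethod("show", "ProvImage", function(object) {
  cat(sprintf("ProvImage %dx%d <%s>, %d history event(s)\n",
              nrow(object@pixels), ncol(object@pixels), object@dtype,
              length(object@history@events)))
  cat("  ", object@history@creation, "\n", sep = "")
  invisible(NULL)
})

#' Unary arithmetic on a ProvImage yields a bare matrix
#'
#' \code{-image} returns a plain signed matrix (unsigned dtypes are promoted
#' to signed integers first, so negation cannot underflow). The result
#' carries no history: it is raw numeric material, typically used as a
#' watershed landscape. This supports the \code{watershed_with_seeds(-wall,
#' seeds = s)} idiom, where the seeds -- the first history-carrying argument
#' -- donate the provenance chain.
#'
#' @param e1 a \linkS4class{ProvImage}.
#' @param e2 missing.
#' @return A plain integer or double matrix.
#' @export
setMethod("Arith", signature("ProvImage", "missing"), function(e1, e2) {
  p <- e1@pixels
  if (is.logical(p)) p <- matrix(as.integer(p), nrow = nrow(p))
  callGeneric(p)
})

# ---- PNG encoding -----------------------------------------------------------

# map pixels to integer 0..255 per the published policy:
# logical -> 0/255; uint8 passthrough; anything else min-max rescaled with
# round-half-up (constant image -> all 0)
.to_uint8 <- function(m, dtype) {
  if (dtype == "logical") return(matrix(ifelse(m, 255L, 0L), nrow = nrow(m)))
  if (dtype == "uint8") return(m)
  lo <- min(m)
  hi <- max(m)
  if (hi == lo) return(matrix(0L, nrow(m), ncol(m)))
  matrix(as.integer(floor((m - lo) / (hi - lo) * 255 + 0.5)), nrow = nrow(m))
}

#' @rdname encodePng
#' @export
setMethod("encodePng", "ProvImage", function(x, ...) {
  m <- .to_uint8(x@pixels, x@dtype)
  png::writePNG(m / 255, target = raw())
})

#' @rdname encodePng
#' @export
setMethod("encodePng", "matrix", function(x, ...) {
  m <- .to_uint8(x, .infer_dtype(x))
  png::writePNG(m / 255, target = raw())
})

#' Decode PNG bytes to 8-bit values
#'
#' Inverse of \code{\link{encodePng}} for 8-bit content: grayscale PNGs
#' decode to an integer matrix in [0, 255], RGB PNGs to an integer
#' \code{h x w x 3} array.
#'
#' @param bytes raw vector of PNG bytes.
#' @return Integer matrix or array of values in [0, 255].
#' @export
decodePng <- function(bytes) {
  m <- png::readPNG(bytes)
  out <- as.integer(round(m * 255))
  dim(out) <- dim(m)
  out
}

# ---- 3D stacks --------------------------------------------------------------

#' 3D stack of identically shaped slices
#'
#' Voxels are ordered (z, row, col). All constituent slices must share shape
#' and dtype; the creation record lists the source slices in order.
#'
#' @slot voxels 3D array ordered (z, row, col).
#' @slot dtype shared slice dtype.
#' @slot history the \linkS4class{ImageHistory}.
#' @export
setClass("Stack3D",
  representation(voxels = "array", dtype = "character",
                 history = "ImageHistory"))

setValidity("Stack3D", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array (z, row, col)")
  TRUE
})

#' Assemble a 3D stack from 2D slices
#'
#' @param slices non-empty list of \linkS4class{ProvImage}s of identical
#'   shape and dtype, in z order.
#' @return A \linkS4class{Stack3D} with \code{voxels[k, , ]} equal to the
#'   pixels of \code{slices[[k]]}.
#' @export
stackFromSlices <- function(slices) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("slices must be a non-empty list of ProvImage objects", call. = FALSE)
  if (!all(vapply(slices, is, logical(1), class2 = "ProvImage")))
    stop("all slices must be ProvImage objects", call. = FALSE)
  shp <- dim(slices[[1]]@pixels)
  dt <- slices[[1]]@dtype
  for (s in slices) {
    if (!identical(dim(s@pixels), shp))
      stop("slice shape mismatch", call. = FALSE)
    if (!identical(s@dtype, dt))
      stop("slice dtype mismatch", call. = FALSE)
  }
  vox <- array(vector(typeof(slices[[1]]@pixels), 0),
               dim = c(length(slices), shp))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]@pixels
  srcs <- vapply(slices, function(s) s@history@creation, character(1))
  new("Stack3D", voxels = vox, dtype = dt,
      history = ImageHistory(paste0("Stack from ", length(slices),
                                    " slices: ", paste(srcs, collapse = "; "))))
}

#' @rdname pixels
#' @export
setMethod("pixels", "Stack3D", function(x) x@voxels)

#' @rdname provenance
#' @export
setMethod("provenance", "Stack3D", function(x) x@history)

#' @rdname creation
#' @export
setMethod("creation", "Stack3D", function(x) x@history@creation)

#' @rdname dtype
#' @export
setMethod("dtype", "Stack3D", function(x) x@dtype)

setMethod("show", "Stack3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Stack3D %d z-slices of %dx%d <%s>\n", d[1], d[2], d[3],
              object@dtype))
  invisible(NULL)
})
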