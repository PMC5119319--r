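#' @include provimage-package.R
NULL

#' Pixel values of an image-like object
#'
#' @param x a \linkS4class{ProvImage}, \linkS4class{SegmentedImage},
#'   \linkS4class{Stack3D} or \linkS4class{Region}.
#' @return The underlying matrix (or 3D array for a stack).
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Provenance history of an object
#'
#' @param x an object carrying an \linkS4class{ImageHistory}.
#' @return The \linkS4class{ImageHistory}.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Creation record of an object's history
#' @param x an object carrying a history, or an \linkS4class{ImageHistory}.
#' @return Single character string naming the source.
#' @export
setGeneric("creation", function(x) standardGeneric("creation"))

#' Transformation events of an object's history
#' @param x an object carrying a history, or an \linkS4class{ImageHistory}.
#' @return Character vector of call-style event strings, in application order.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Stored value type of an image
#' @param x a \linkS4class{ProvImage} or \linkS4class{Stack3D}.
#' @return One of \code{"logical"}, \code{"uint8"}, \code{"uint16"},
#'   \code{"integer"}, \code{"double"}.
#' @export
setGeneric("dtype", function(x) standardGeneric("dtype"))

#' Encode an image as PNG bytes
#'
#' Booleans map FALSE to 0 and TRUE to 255; 8-bit values pass through
#' unchanged; 16-bit and floating-point values are min-max rescaled so the
#' minimum maps to 0 and the maximum to 255 (a constant image encodes as all
#' zeros). Encoding is pure: the same object always yields byte-identical
#' output.
#'
#' @param x a \linkS4class{ProvImage} or a plain 2D matrix.
#' @param ... unused.
#' @return Raw vector holding a decodable PNG byte stream.
#' @export
setGeneric("encodePng", function(x, ...) standardGeneric("encodePng"))

#' Label matrix of a segmentation
#' @param x a \linkS4class{SegmentedImage}.
#' @return Integer matrix; 0 is background, each positive value one segment.
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))

#' Segment identifiers present in a segmentation
#' @param x a \linkS4class{SegmentedImage}.
#' @return Sorted integer vector of the distinct positive labels.
#' @export
setGeneric("identifiers", function(x) standardGeneric("identifiers"))

#' Extract one segment as a Region
#' @param x a \linkS4class{SegmentedImage}.
#' @param i a positive integer present in \code{identifiers(x)}.
#' @return A \linkS4class{Region} whose mask is \code{labels2d(x) == i}.
#' @export
setGeneric("regionByIdentifier", function(x, i) standardGeneric("regionByIdentifier"))

#' Remove one segment from a segmentation
#'
#' Pixels carrying label \code{i} are set to background (0). Remaining labels
#' are not renumbered.
#'
#' @param x a \linkS4class{SegmentedImage}.
#' @param i a positive integer present in \code{identifiers(x)}.
#' @return The modified \linkS4class{SegmentedImage}.
#' @export
setGeneric("removeRegion", function(x, i) standardGeneric("removeRegion"))

#' Region area
#' @param x a \linkS4class{Region}.
#' @return Number of member (TRUE) pixels.
#' @export
setGeneric("area", function(x) standardGeneric("area"))

#' Region perimeter
#'
#' Defined as the number of border pixels (the 1-pixel-thick inner boundary).
#' Alternative definitions (crack length, weighted contour) exist in the
#' literature; this package pins the border-pixel count.
#'
#' @param x a \linkS4class{Region}.
#' @return Non-negative integer.
#' @export
setGeneric("perimeter", function(x) standardGeneric("perimeter"))

#' Inner part of a region
#'
#' Morphological erosion of the mask by the 3x3 cross structuring element
#' (image borders behave as if padded FALSE).
#'
#' @param x a \linkS4class{Region}.
#' @return A \linkS4class{Region}; always a subset of \code{x}.
#' @export
setGeneric("inner", function(x) standardGeneric("inner"))

#' Border of a region
#'
#' The member pixels that are not in \code{inner(x)}: the 1-pixel-thick inner
#' boundary. \code{border} and \code{inner} partition the mask.
#'
#' @param x a \linkS4class{Region}.
#' @return A \linkS4class{Region}.
#' @export
setGeneric("border", function(x) standardGeneric("border"))

#' Filled convex hull of a region
#'
#' The hull is taken over the unit squares of the member pixels (each pixel
#' contributes its four corners); a pixel belongs to the hull region when its
#' centre lies inside or on the hull polygon. The hull always contains the
#' mask and is idempotent.
#'
#' @param x a \linkS4class{Region}.
#' @return A \linkS4class{Region}.
#' @export
setGeneric("convexHull", function(x) standardGeneric("convexHull"))

#' Region centroid
#'
#' Arithmetic mean of the member pixel (row, col) coordinates, 1-based.
#'
#' @param x a \linkS4class{Region}.
#' @return Numeric vector \code{c(row, col)}; \code{NaN}s for an empty mask.
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' Dilate a region
#'
#' Morphological dilation of the mask by the 3x3 cross, clipped at the image
#' edge (shape-preserving).
#'
#' @param x a \linkS4class{Region}.
#' @return A \linkS4class{Region}; always a superset of \code{x}.
#' @export
setGeneric("dilate", function(x) standardGeneric("dilate"))

#' False-colour PNG of a segmentation
#'
#' Background pixels are black; each segment is uniformly coloured with
#' \code{\link{pretty_color_from_identifier}}, so the encoding is
#' byte-identical across runs and platforms.
#'
#' @param x a \linkS4class{SegmentedImage}.
#' @return Raw vector holding an 8-bit RGB PNG byte stream.
#' @export
setGeneric("falseColourPng", function(x) standardGeneric("falseColourPng"))

#' Fetch one 2D slice from a microscopy collection
#'
#' @param x a \linkS4class{MicroscopyCollection}.
#' @param s,c,z,t series, channel, z-slice and time point (all default 0).
#' @return A \linkS4class{ProvImage} whose creation record names the cached
#'   slice file.
#' @export
setGeneric("getImage", function(x, s = 0L, c = 0L, z = 0L, t = 0L)
  standardGeneric("getImage"))

#' Fetch a z-stack from a microscopy collection
#'
#' All slices for the given (series, channel, time point), ordered by
#' ascending z. The z coordinates must be contiguous; a gap is an error.
#'
#' @param x a \linkS4class{MicroscopyCollection}.
#' @param s,c,t series, channel and time point (all default 0).
#' @return A \linkS4class{Stack3D} with voxels ordered (z, row, col).
#' @export
setGeneric("getZStack", function(x, s = 0L, c = 0L, t = 0L)
  standardGeneric("getZStack"))
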