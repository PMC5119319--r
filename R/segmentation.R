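#' @include transforms.R
NULL

#' Labelled segmentation of a 2D image
#'
#' A 2D array of non-negative integer labels with a provenance history.
#' 0 is background; every positive value present defines exactly one segment.
#' Audit snapshots of segmentations use the false-colour encoding.
#'
#' @slot labels integer matrix of non-negative labels.
#' @slot history the \linkS4class{ImageHistory}.
#' @export
setClass("SegmentedImage",
  representation(labels = "matrix", history = "ImageHistory"))

setValidity("SegmentedImage", function(object) {
  l <- object@labels
  if (!is.integer(l)) return("labels must be an integer matrix")
  if (length(dim(l)) != 2L || nrow(l) < 1L || ncol(l) < 1L)
    return("labels must be a 2D matrix with positive extents")
  if (any(l < 0L)) return("labels must be non-negative")
  TRUE
})

#' Construct a SegmentedImage
#'
#' @param labels integer matrix of non-negative labels (0 = background).
#' @param history an \linkS4class{ImageHistory}; by default a fresh one.
#' @return A \linkS4class{SegmentedImage}.
#' @export
SegmentedImage <- function(labels,
                           history = ImageHistory("SegmentedImage from labels")) {
  if (is.logical(labels) || is.double(labels))
    labels <- matrix(as.integer(labels), nrow = nrow(labels))
  new("SegmentedImage", labels = labels, history = history)
}

#' @rdname labels2d
#' @export
setMethod("labels2d", "SegmentedImage", function(x) x@labels)

#' @rdname pixels
#' @export
setMethod("pixels", "SegmentedImage", function(x) x@labels)

#' @rdname provenance
#' @export
setMethod("provenance", "SegmentedImage", function(x) x@history)

#' @rdname creation
#' @export
setMethod("creation", "SegmentedImage", function(x) x@history@creation)

#' @rdname events
#' @export
setMethod("events", "SegmentedImage", function(x) x@history@events)

setMethod("dim", "SegmentedImage", function(x) dim(x@labels))

setMethod("show", "SegmentedImage", function(object) {
  ids <- identifiers(object)
  cat(sprintf("SegmentedImage %dx%d, %d segment(s)\n",
              nrow(object@labels), ncol(object@labels), length(ids)))
  invisible(NULL)
})

#' @rdname identifiers
#' @export
setMethod("identifiers", "SegmentedImage", function(x) {
  v <- sort(unique(as.vector(x@labels)))
  v[v > 0L]
})

#' @rdname regionByIdentifier
#' @export
setMethod("regionByIdentifier", "SegmentedImage", function(x, i) {
  i <- as.integer(i)
  if (length(i) != 1L || !(i %in% identifiers(x)))
    stop("no segment with identifier ", i, "; present: ",
         paste(identifiers(x), collapse = ", "), call. = FALSE)
  Region(x@labels == i)
})

#' @rdname removeRegion
#' @export
setMethod("removeRegion", "SegmentedImage", function(x, i) {
  i <- as.integer(i)
  if (length(i) != 1L || !(i %in% identifiers(x)))
    stop("no segment with identifier ", i, "; present: ",
         paste(identifiers(x), collapse = ", "), call. = FALSE)
  x@labels[x@labels == i] <- 0L
  x
})

# ---- segmentation algorithms -----------------------------------------------

#' Audited segmentation transforms
#'
#' \code{connected_components(image, background)} labels maximal 8-connected
#' groups of equal-valued pixels (excluding the background value) with
#' distinct consecutive positive labels 1..K, assigned in raster (row-major)
#' order of each component's first pixel; background-valued pixels map to 0.
#'
#' \code{watershed_with_seeds(landscape, seeds, mask)} grows basins from the
#' seed labels by priority flood: pixels are claimed in order of ascending
#' landscape value, ties broken by flooding order (first queued wins; the
#' queue is ordered by (value, insertion sequence), growth is 4-connected).
#' Every unmasked pixel receives exactly one seed's label -- there are no
#' watershed-line pixels and no zeros outside the mask; where \code{mask} is
#' FALSE pixels stay 0. On flat terrain the flood reduces to multi-source
#' BFS, i.e. Manhattan-distance propagation from the seeds.
#'
#' Both are decorated transformations: they append a history event and write
#' a false-colour audit snapshot. The landscape may be a bare matrix (the
#' usual case: \code{-wall_image}, since unary minus on a
#' \linkS4class{ProvImage} yields a plain signed matrix); the history is then
#' donated by \code{seeds}, chaining the full pipeline provenance.
#'
#' @param image binary or labelled image (ProvImage, SegmentedImage or
#'   matrix).
#' @param background the pixel value treated as background (default 0;
#'   FALSE for logical input).
#' @param landscape numeric matrix or ProvImage: the topography to flood.
#' @param seeds a \linkS4class{SegmentedImage} with at least one segment.
#' @param mask optional boolean image; FALSE pixels are never labelled.
#' @return A \linkS4class{SegmentedImage}.
#' @examples
#' old <- auditEnabled(FALSE)
#' m <- matrix(c(1L,0L,0L, 1L,0L,1L, 0L,0L,1L), 3, 3)
#' identifiers(connected_components(imageFromArray(m, "demo"), background = 0))
#' auditEnabled(old)
#' @name segmentation-transforms
NULL

#' @rdname segmentation-transforms
#' @export
connected_components <- transformation(function(image, background = 0) {
  m <- .pixels_of(image)
  if (is.logical(m)) {
    m <- matrix(as.integer(m), nrow = nrow(m))
    background <- as.integer(as.logical(background))
  }
  if (is.double(m)) {
    if (any(m != round(m)))
      stop("connected_components requires integer or boolean input",
           call. = FALSE)
    m <- matrix(as.integer(m), nrow = nrow(m))
  }
  SegmentedImage(.cc_label(m, as.integer(background)))
}, "connected_components")

#' @rdname segmentation-transforms
#' @export
watershed_with_seeds <- transformation(function(landscape, seeds, mask = NULL) {
  land <- .pixels_of(landscape)
  storage.mode(land) <- "double"
  if (!is(seeds, "SegmentedImage"))
    stop("seeds must be a SegmentedImage", call. = FALSE)
  sl <- seeds@labels
  if (!identical(dim(land), dim(sl)))
    stop("landscape and seeds must have the same shape", call. = FALSE)
  if (length(identifiers(seeds)) == 0L)
    stop("seeds must contain at least one segment", call. = FALSE)
  mk <- NULL
  if (!is.null(mask)) {
    mk <- .binary_of(mask)
    if (!identical(dim(mk), dim(sl)))
      stop("mask shape mismatch", call. = FALSE)
  }
  SegmentedImage(.watershed_flood(land, sl, mk))
}, "watershed_with_seeds")
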