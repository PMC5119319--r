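#' @include AllGenerics.R
NULL

#' Provenance history of an image
#'
#' A history is a creation record (a single string naming the source: a file
#' path or a generator description, set exactly once at construction) plus an
#' ordered list of transformation events. Events are stored by their string
#' form \code{"function_name(arg1, arg2, ...)"} -- a history is essentially a
#' list of strings, so it serialises as plain text and compares by value. The
#' event list only ever grows by appending; its order is application order.
#'
#' @slot creation single character string.
#' @slot events character vector of call-style event strings.
#' @export
setClass("ImageHistory",
  representation(creation = "character", events = "character"),
  prototype(creation = NA_character_, events = character(0)))

setValidity("ImageHistory", function(object) {
  if (length(object@creation) != 1L || is.na(object@creation))
    return("creation must be a single non-NA string")
  TRUE
})

#' Construct an ImageHistory
#'
#' @param creation single string naming the source of the image.
#' @param events character vector of event strings (default empty).
#' @return An \linkS4class{ImageHistory}.
#' @examples
#' h <- ImageHistory("synthetic 2x2 zeros")
#' creation(h)
#' @export
ImageHistory <- function(creation, events = character(0)) {
  new("ImageHistory", creation = as.character(creation),
      events = as.character(events))
}

#' @rdname creation
#' @export
setMethod("creation", "ImageHistory", function(x) x@creation)

#' @rdname events
#' @export
setMethod("events", "ImageHistory", function(x) x@events)

setMethod("show", "ImageHistory", function(object) {
  cat(object@creation, "\n")
  for (e in object@events) cat("<Event(", e, ")>\n", sep = "")
  invisible(NULL)
})

# append one event; internal -- all growth goes through here so the
# append-only invariant holds by construction
.history_append <- function(history, event) {
  history@events <- c(history@events, event)
  history
}
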