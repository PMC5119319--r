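#' @include image.R
NULL

# package-global audit state: one counter shared by all decorated functions,
# so a pipeline's snapshots number 1..n in call order
.audit <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  assign("enabled", TRUE, envir = .audit)
  assign("directory", NULL, envir = .audit)  # NULL = working directory
  assign("counter", 1L, envir = .audit)
  registerConverter("tifdir", tifdirConverter)
  registerConverter("bfconvert", bfconvertConverter)
}

#' Audit-trail configuration
#'
#' Every call to a decorated transformation writes its result to
#' \code{{counter}_{function_name}.png} (no zero padding) in the audit
#' directory, then increments the shared counter. \code{auditEnabled} toggles
#' the writing (history recording is unaffected), \code{auditDirectory} sets
#' the destination (default: the current working directory), and
#' \code{resetAudit} resets the counter to 1.
#'
#' @param enabled logical; omit to query the current state.
#' @param directory path; omit to query. \code{NULL} means the working
#'   directory at the time each snapshot is written.
#' @return The current (possibly just-set) value, invisibly for setters.
#' @examples
#' old <- auditEnabled(FALSE)
#' auditEnabled(old)
#' @export
auditEnabled <- function(enabled) {
  old <- get("enabled", envir = .audit)
  if (missing(enabled)) return(old)
  stopifnot(is.logical(enabled), length(enabled) == 1L, !is.na(enabled))
  assign("enabled", enabled, envir = .audit)
  invisible(old)
}

#' @rdname auditEnabled
#' @export
auditDirectory <- function(directory) {
  old <- get("directory", envir = .audit)
  if (missing(directory)) return(old)
  assign("directory", directory, envir = .audit)
  invisible(old)
}

#' @rdname auditEnabled
#' @export
resetAudit <- function() {
  assign("counter", 1L, envir = .audit)
  invisible(1L)
}

#' @rdname auditEnabled
#' @export
auditCounter <- function() get("counter", envir = .audit)

.audit_write <- function(result, name) {
  if (!get("enabled", envir = .audit)) return(invisible(NULL))
  dir <- get("directory", envir = .audit)
  if (is.null(dir)) dir <- getwd()
  if (!dir.exists(dir))
    stop("audit directory does not exist: ", dir, call. = FALSE)
  counter <- get("counter", envir = .audit)
  path <- file.path(dir, sprintf("%d_%s.png", counter, name))
  bytes <- if (is(result, "SegmentedImage")) falseColourPng(result)
           else encodePng(result)
  writeBin(bytes, path)
  assign("counter", counter + 1L, envir = .audit)
  invisible(path)
}

# call-style rendering of one argument: image-valued arguments (anything
# carrying pixels, including bare matrices) render as the literal token
# `image`; everything else is deparsed verbatim
.render_arg <- function(a) {
  if (is(a, "ProvImage") || is(a, "SegmentedImage") || is(a, "Region") ||
      is.matrix(a))
    "image"
  else deparse1(a)
}

.render_event <- function(name, args) {
  nms <- names(args)
  if (is.null(nms)) nms <- rep("", length(args))
  parts <- vapply(seq_along(args), function(i) {
    s <- .render_arg(args[[i]])
    if (nzchar(nms[i])) paste0(nms[i], "=", s) else s
  }, character(1))
  paste0(name, "(", paste(parts, collapse = ", "), ")")
}

# coerce a transform's return value into a history-carrying object
.as_result_image <- function(out, name) {
  if (is(out, "SegmentedImage") || is(out, "ProvImage")) return(out)
  if (is.matrix(out) && (is.logical(out) || is.numeric(out)))
    return(imageFromArray(out, paste0("created by ", name)))
  stop("transformation '", name, "' must return a 2D image", call. = FALSE)
}

#' Decorate a function as an audited transformation
#'
#' Wraps an image-to-image function so that each call (a) coerces the return
#' value to a \linkS4class{ProvImage} (or keeps a
#' \linkS4class{SegmentedImage}); (b) copies the history of the first
#' history-carrying argument and appends one event rendering the call
#' (image-valued arguments as the token \code{image}, positional values
#' verbatim, keyword arguments as \code{name=value}); and (c) if auditing is
#' enabled, writes \code{{counter}_{name}.png} to the audit directory
#' (segmentations use their false-colour encoding) and increments the shared
#' counter.
#'
#' When no argument carries a history (e.g. a bare matrix input), a fresh
#' history with creation record \code{"created by <name>"} is started.
#'
#' @param fun function whose first argument is an image (or bare 2D matrix)
#'   and which returns a 2D array-like result.
#' @param name the function name used in events and audit filenames.
#' @return The decorated function.
#' @examples
#' double_it <- transformation(function(image, k) pixels(image) * k, "double_it")
#' old <- auditEnabled(FALSE)
#' img <- imageFromArray(matrix(1, 2, 2), "demo")
#' events(double_it(img, 2))
#' auditEnabled(old)
#' @export
transformation <- function(fun, name = deparse(substitute(fun))) {
  force(fun)
  force(name)
  function(...) {
    args <- list(...)
    donor <- NULL
    for (a in args) {
      if (is(a, "ProvImage") || is(a, "SegmentedImage")) {
        donor <- provenance(a)
        break
      }
    }
    res <- .as_result_image(fun(...), name)
    hist <- if (is.null(donor)) ImageHistory(paste0("created by ", name))
            else donor
    res@history <- .history_append(hist, .render_event(name, args))
    .audit_write(res, name)
    res
  }
}
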