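#' @include image.R
NULL

#' Content-address key for an input file
#'
#' The 32-character lowercase hex MD5 digest of the input's bytes: identical
#' content gives an identical key regardless of filename, so converted slices
#' are cached once per distinct input. For a directory input the key is the
#' MD5 of a manifest listing each contained file's name and content digest
#' (sorted by relative path), so any change to names or bytes changes the
#' key.
#'
#' @param path readable file or directory.
#' @return 32-character lowercase hex string.
#' @examples
#' f <- tempfile(); writeLines(character(0), f)
#' @export
cacheKey <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, recursive = TRUE))
    if (length(files) == 0L) stop("empty directory: ", path, call. = FALSE)
    sums <- tools::md5sum(file.path(path, files))
    manifest <- tempfile()
    on.exit(unlink(manifest))
    writeLines(paste(files, unname(sums)), manifest)
    return(unname(tools::md5sum(manifest)))
  }
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  key <- unname(tools::md5sum(path))
  if (is.na(key)) stop("cannot read file: ", path, call. = FALSE)
  key
}

# ---- slice filename scheme --------------------------------------------------

.SLICE_RE <- "^S([0-9]+)_C([0-9]+)_Z([0-9]+)_T([0-9]+)\\.tif$"

#' Parse and format slice filenames
#'
#' Cached slices follow the naming scheme \code{S{s}_C{c}_Z{z}_T{t}.tif}
#' (no zero padding, uppercase letters, \code{.tif} extension).
#' \code{parseSliceFilename} inverts the scheme; a non-conforming name is a
#' parse error.
#'
#' @param name slice filename (a path is reduced to its basename).
#' @param s,c,z,t non-negative integer coordinates.
#' @return \code{parseSliceFilename}: named integer vector
#'   \code{c(s, c, z, t)}. \code{formatSliceFilename}: the filename string.
#' @examples
#' parseSliceFilename("S0_C1_Z31_T0.tif")
#' formatSliceFilename(0, 1, 31, 0)
#' @export
parseSliceFilename <- function(name) {
  name <- basename(name)
  m <- regmatches(name, regexec(.SLICE_RE, name))[[1]]
  if (length(m) != 5L)
    stop("filename does not follow the S{s}_C{c}_Z{z}_T{t}.tif scheme: ",
         name, call. = FALSE)
  out <- as.integer(m[2:5])
  names(out) <- c("s", "c", "z", "t")
  out
}

#' @rdname parseSliceFilename
#' @export
formatSliceFilename <- function(s, c, z, t) {
  stopifnot(s >= 0, c >= 0, z >= 0, t >= 0)
  sprintf("S%d_C%d_Z%d_T%d.tif", as.integer(s), as.integer(c),
          as.integer(z), as.integer(t))
}

# ---- converters -------------------------------------------------------------

.converters <- new.env(parent = emptyenv())

#' Register or fetch a slice converter
#'
#' A converter is a function \code{f(input, outdir)} that populates
#' \code{outdir} with 2D grayscale TIFF slices named
#' \code{S{s}_C{c}_Z{z}_T{t}.tif}. Two converters are built in:
#' \describe{
#'   \item{\code{"tifdir"}}{treats an input directory (or zip archive) of
#'     already-named slice TIFFs as pre-converted and copies them into the
#'     cache; this self-contained path needs no external tools.}
#'   \item{\code{"bfconvert"}}{shells out to the external Bio-Formats
#'     \code{bfconvert} binary to unpack native microscopy formats (e.g.
#'     CZI); optional -- a clear error names the \code{tifdir} alternative
#'     when the binary is absent.}
#' }
#'
#' @param name converter name.
#' @param fun converter function; omit to fetch the registered converter.
#' @return \code{registerConverter} returns \code{fun} invisibly;
#'   \code{getConverter} returns the function.
#' @export
registerConverter <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .converters)
  invisible(fun)
}

#' @rdname registerConverter
#' @export
getConverter <- function(name) {
  if (!exists(name, envir = .converters))
    stop("unknown converter '", name, "'; registered: ",
         paste(ls(.converters), collapse = ", "), call. = FALSE)
  get(name, envir = .converters)
}

#' @rdname registerConverter
#' @export
tifdirConverter <- function(input, outdir) {
  src <- input
  if (!dir.exists(input)) {
    if (grepl("\\.zip$", tolower(input)) && file.exists(input)) {
      src <- tempfile("tifdir_unzip_")
      dir.create(src)
      utils::unzip(input, exdir = src)
    } else {
      stop("tifdir converter expects a directory or .zip of slice TIFFs: ",
           input, call. = FALSE)
    }
  }
  files <- list.files(src, pattern = "\\.tif$", recursive = TRUE,
                      full.names = TRUE)
  ok <- grepl(.SLICE_RE, basename(files))
  if (any(!ok))
    warning("skipping ", sum(!ok), " non-conforming file(s) in ", input,
            call. = FALSE)
  files <- files[ok]
  if (length(files) == 0L)
    stop("no parseable S*_C*_Z*_T*.tif slices in ", input, call. = FALSE)
  for (f in files) file.copy(f, file.path(outdir, basename(f)))
  invisible(file.path(outdir, basename(files)))
}

#' @rdname registerConverter
#' @export
bfconvertConverter <- function(input, outdir) {
  exe <- Sys.which("bfconvert")
  if (!nzchar(exe))
    stop("bfconvert not found on PATH. Install the Bio-Formats command-line ",
         "tools, or use the self-contained 'tifdir' converter with a ",
         "directory of S{s}_C{c}_Z{z}_T{t}.tif slices.", call. = FALSE)
  pattern <- file.path(outdir, "S%s_C%c_Z%z_T%t.tif")
  status <- system2(exe, c(shQuote(input), shQuote(pattern)),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L)
    stop("bfconvert failed (exit ", code, "):\n",
         paste(status, collapse = "\n"), call. = FALSE)
  invisible(list.files(outdir, full.names = TRUE))
}

# ---- collection -------------------------------------------------------------

#' Collection of 2D microscopy slices
#'
#' Maps (series, channel, z, time) coordinates to cached slice files. Every
#' image fetched from a collection has a creation record naming the cached
#' file -- which lives under the content-hash directory -- so provenance
#' chains back to the source bytes. Coordinate sets are the observed ones;
#' no dense ranges are inferred.
#'
#' @slot source original input path.
#' @slot cacheDir the cache subdirectory holding the slices.
#' @slot entries data.frame with columns \code{s, c, z, t, path}.
#' @slot converted TRUE when this load ran the converter (cold cache).
#' @export
setClass("MicroscopyCollection",
  representation(source = "character", cacheDir = "character",
                 entries = "data.frame", converted = "logical"))

setValidity("MicroscopyCollection", function(object) {
  e <- object@entries
  need <- c("s", "c", "z", "t", "path")
  if (!all(need %in% names(e))) return("entries must have s, c, z, t, path")
  if (anyDuplicated(e[, c("s", "c", "z", "t")]))
    return("duplicate slice coordinates")
  TRUE
})

setMethod("show", "MicroscopyCollection", function(object) {
  e <- object@entries
  cat(sprintf("MicroscopyCollection: %d slice(s) from %s\n", nrow(e),
              object@source))
  cat(sprintf("  series %s | channels %s | z %s | timepoints %s\n",
              paste(sort(unique(e$s)), collapse = ","),
              paste(sort(unique(e$c)), collapse = ","),
              paste(range(e$z), collapse = ".."),
              paste(sort(unique(e$t)), collapse = ",")))
  invisible(NULL)
})

.index_cache_dir <- function(dir, source, converted) {
  files <- list.files(dir, pattern = "\\.tif$")
  ok <- grepl(.SLICE_RE, files)
  if (any(!ok))
    warning("skipping ", sum(!ok), " non-conforming cached file(s) in ", dir,
            call. = FALSE)
  files <- files[ok]
  if (length(files) == 0L)
    stop("no parseable slices found for ", source,
         " (empty collection)", call. = FALSE)
  coords <- t(vapply(files, parseSliceFilename, integer(4)))
  entries <- data.frame(s = coords[, 1], c = coords[, 2], z = coords[, 3],
                        t = coords[, 4],
                        path = file.path(dir, files),
                        stringsAsFactors = FALSE, row.names = NULL)
  entries <- entries[order(entries$s, entries$c, entries$t, entries$z), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  new("MicroscopyCollection", source = source, cacheDir = dir,
      entries = entries, converted = converted)
}

#' Load a bioimage into a cached collection of 2D slices
#'
#' The input is unpacked once into
#' \code{<backendRoot>/<md5 of input bytes>/S{s}_C{c}_Z{z}_T{t}.tif}. When
#' the cache subdirectory already holds slices, no conversion runs -- the
#' conversion only ever happens once per distinct input content.
#'
#' @param path input file (or slice directory/zip for the \code{tifdir}
#'   converter).
#' @param backendRoot cache root directory; defaults to option
#'   \code{provimage.backend_root}, falling back to
#'   \code{./provimage_backend}. Created if needed.
#' @param converter converter name (\code{"tifdir"} or \code{"bfconvert"}) or
#'   a converter function.
#' @return A \linkS4class{MicroscopyCollection}; its \code{converted} slot
#'   records whether this call ran the converter.
#' @export
loadCollection <- function(path,
                           backendRoot = getOption("provimage.backend_root",
                                                   "./provimage_backend"),
                           converter = "tifdir") {
  fun <- if (is.function(converter)) converter else getConverter(converter)
  key <- cacheKey(path)
  dir <- file.path(backendRoot, key)
  converted <- FALSE
  if (!dir.exists(dir) || length(list.files(dir)) == 0L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fun(path, dir)
    converted <- TRUE
  }
  .index_cache_dir(dir, source = path, converted = converted)
}

.lookup_slice <- function(x, s, c, z, t) {
  e <- x@entries
  hit <- e$s == s & e$c == c & e$z == z & e$t == t
  if (!any(hit)) {
    stop(sprintf(
      "no slice at (s=%d, c=%d, z=%d, t=%d); available: series {%s}, channels {%s}, z {%s}, timepoints {%s}",
      s, c, z, t,
      paste(sort(unique(e$s)), collapse = ","),
      paste(sort(unique(e$c)), collapse = ","),
      paste(sort(unique(e$z)), collapse = ","),
      paste(sort(unique(e$t)), collapse = ",")), call. = FALSE)
  }
  e$path[hit][1]
}

#' @rdname getImage
#' @export
setMethod("getImage", "MicroscopyCollection", function(x, s = 0L, c = 0L,
                                                       z = 0L, t = 0L) {
  imageFromFile(.lookup_slice(x, as.integer(s), as.integer(c), as.integer(z),
                              as.integer(t)))
})

#' @rdname getZStack
#' @export
setMethod("getZStack", "MicroscopyCollection", function(x, s = 0L, c = 0L,
                                                        t = 0L) {
  e <- x@entries
  hit <- e$s == as.integer(s) & e$c == as.integer(c) & e$t == as.integer(t)
  if (!any(hit))
    stop(sprintf("no slices at (s=%d, c=%d, t=%d)", s, c, t), call. = FALSE)
  zs <- sort(e$z[hit])
  if (!identical(zs, seq(min(zs), by = 1L, length.out = length(zs))))
    stop("z coordinates are not contiguous: ", paste(zs, collapse = ","),
         call. = FALSE)
  slices <- lapply(zs, function(z) getImage(x, s = s, c = c, z = z, t = t))
  stackFromSlices(slices)
})

#' Number of slices in a collection
#' @param x a \linkS4class{MicroscopyCollection}.
#' @return Integer slice count.
#' @export
setMethod("length", "MicroscopyCollection", function(x) nrow(x@entries))
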