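#' @include fixtures.R annotate.R
NULL

#' Seeded-watershed cell-segmentation demo
#'
#' The end-to-end workflow: load a slice collection, pick the cell-wall
#' channel/z-slice, then run the audited six-step pipeline
#' \enumerate{
#'   \item \code{threshold_abs(wall, cutoff)} -- wall mask (strict >)
#'   \item \code{dilate_binary} -- close small gaps in the walls
#'   \item \code{invert} -- cell interiors (and the surround) become seeds
#'   \item \code{remove_small_objects(min_size = minSize)} -- drop specks
#'   \item \code{connected_components(background = 0)} -- label the seeds
#'   \item \code{watershed_with_seeds(-wall, seeds = seeds)} -- grow cells
#' }
#' followed by an (undecorated) area filter that removes every region larger
#' than \code{maxArea} pixels -- regions too large to be cells, e.g. the
#' non-tissue surround. Each decorated step writes its numbered PNG snapshot
#' into \code{outputDir} (\code{1_threshold_abs.png} ...
#' \code{6_watershed_with_seeds.png}). The demo then writes
#' \code{annotation.png} (each surviving cell outlined in its deterministic
#' pretty colour, with its pixel area printed at its centroid) and
#' \code{cells.tsv} (identifier, area, centroid_row, centroid_col) and prints
#' the final cell count.
#'
#' @param input path accepted by \code{\link{loadCollection}}.
#' @param outputDir directory for audit PNGs, annotation and table (created
#'   if needed).
#' @param cutoff absolute threshold for the wall mask (default 50).
#' @param minSize smallest retained seed area in pixels (default 500).
#' @param maxArea regions above this area are removed (default 40000).
#' @param channel wall-marker channel (default 1).
#' @param zslice z-slice; default 31 when available, otherwise the middle of
#'   the available z range.
#' @param backendRoot cache root for \code{\link{loadCollection}}.
#' @param converter converter name or function.
#' @param textColor colour of the burned-in area labels (default white).
#' @return Invisibly, a list with \code{count}, \code{segmentation},
#'   \code{table} (the per-cell data.frame), \code{collection} and
#'   \code{files} (paths written).
#' @export
segmentDemo <- function(input, outputDir, cutoff = 50, minSize = 500,
                        maxArea = 40000, channel = 1L, zslice = NULL,
                        backendRoot = file.path(outputDir, "backend"),
                        converter = "tifdir",
                        textColor = c(255L, 255L, 255L)) {
  stopifnot(cutoff > 0, minSize > 0, maxArea > 0, channel >= 0)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)

  collection <- loadCollection(input, backendRoot = backendRoot,
                               converter = converter)
  e <- collection@entries
  zs <- sort(unique(e$z[e$c == as.integer(channel)]))
  if (length(zs) == 0L)
    stop("channel ", channel, " not present; available channels: ",
         paste(sort(unique(e$c)), collapse = ","), call. = FALSE)
  if (is.null(zslice))
    zslice <- if (31L %in% zs) 31L else zs[ceiling(length(zs) / 2)]
  cellwall <- getImage(collection, c = channel, z = zslice)

  # route the audit trail into outputDir with a fresh counter
  old_enabled <- auditEnabled(TRUE)
  old_dir <- auditDirectory(outputDir)
  on.exit({
    auditEnabled(old_enabled)
    auditDirectory(old_dir)
  })
  resetAudit()

  seeds <- threshold_abs(cellwall, cutoff)
  seeds <- dilate_binary(seeds)
  seeds <- invert(seeds)
  seeds <- remove_small_objects(seeds, min_size = minSize)
  seeds <- connected_components(seeds, background = 0)
  segmentation <- watershed_with_seeds(-cellwall, seeds = seeds)

  # remove regions too large to be cells (e.g. the non-tissue surround)
  for (i in identifiers(segmentation)) {
    region <- regionByIdentifier(segmentation, i)
    if (area(region) > maxArea)
      segmentation <- removeRegion(segmentation, i)
  }

  annotation <- fromGrayscale(cellwall)
  ids <- identifiers(segmentation)
  tab <- data.frame(identifier = integer(0), area = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0))
  for (i in ids) {
    region <- regionByIdentifier(segmentation, i)
    outline <- dilate(border(inner(region)))
    color <- pretty_color_from_identifier(i)
    annotation <- maskRegion(annotation, outline, color)
    cen <- centroid(region)
    annotation <- textAt(annotation, as.character(area(region)), cen,
                         color = textColor, center = TRUE)
    tab <- rbind(tab, data.frame(identifier = i, area = area(region),
                                 centroid_row = cen[1], centroid_col = cen[2],
                                 row.names = NULL))
  }

  annotation_path <- file.path(outputDir, "annotation.png")
  writeBin(annotationPng(annotation), annotation_path)
  table_path <- file.path(outputDir, "cells.tsv")
  write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)

  cat(sprintf("%d cells\n", length(ids)))
  invisible(list(count = length(ids), segmentation = segmentation,
                 table = tab, collection = collection,
                 files = c(annotation_path, table_path)))
}

# ---- command-line entry points ----------------------------------------------

#' Command-line entry points
#'
#' Thin, shell-friendly wrappers over the package functions, used by the
#' \code{inst/scripts/provimage-cli.R} Rscript front end. Each returns an
#' integer exit status (0 = success) instead of raising, and prints
#' human-readable progress.
#'
#' \code{cmdMakeFixture} writes a synthetic collection plus manifest and
#' prints the slice count. \code{cmdConvert} populates the slice cache and
#' prints the cache key and coordinate ranges (a second invocation prints
#' "cached" and performs no conversion). \code{cmdSegmentDemo} runs
#' \code{\link{segmentDemo}} and logs each recorded history event.
#'
#' @param outdir,input,backendRoot,converter paths and converter selection.
#' @param spec a \code{\link{cellGridSpec}} for the fixture.
#' @param ... passed on to \code{\link{segmentDemo}}.
#' @return Integer exit status, invisibly.
#' @name cli
NULL

#' @rdname cli
#' @export
cmdMakeFixture <- function(outdir, spec = cellGridSpec()) {
  status <- tryCatch({
    manifest <- generateCollection(spec, outdir)
    cat(sprintf("%d slices\n", nrow(manifest)))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' @rdname cli
#' @export
cmdConvert <- function(input,
                       backendRoot = getOption("provimage.backend_root",
                                               "./provimage_backend"),
                       converter = "tifdir") {
  status <- tryCatch({
    collection <- loadCollection(input, backendRoot = backendRoot,
                                 converter = converter)
    cat(if (collection@converted) "converted\n" else "cached\n")
    cat(sprintf("cache key: %s\n", basename(collection@cacheDir)))
    show(collection)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' @rdname cli
#' @export
cmdSegmentDemo <- function(input, outdir, ...) {
  status <- tryCatch({
    res <- segmentDemo(input, outdir, ...)
    for (ev in events(res$segmentation)) message("INFO event: ", ev)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Read a YAML configuration file
#'
#' Recognised keys: \code{backend_root} (sets option
#' \code{provimage.backend_root}) and \code{audit: {enabled, directory}}.
#'
#' @param path YAML file.
#' @return Invisibly, the parsed list.
#' @export
readProvimageConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for config files", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$backend_root))
    options(provimage.backend_root = cfg$backend_root)
  if (!is.null(cfg$audit$enabled)) auditEnabled(isTRUE(cfg$audit$enabled))
  if (!is.null(cfg$audit$directory)) auditDirectory(cfg$audit$directory)
  invisible(cfg)
}
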