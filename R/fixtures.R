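#' @include datamanager.R segmentation.R
NULL

#' Specification for a synthetic cell-grid fixture
#'
#' Describes a synthetic confocal-style image of plant tissue: a regular
#' R x C grid of cells whose bright walls (cell-wall marker channel) surround
#' dark interiors, embedded in a surrounding background frame, with a second
#' channel carrying one nuclear-marker blob per cell. Same seed, same spec
#' => byte-identical fixture.
#'
#' The image shape is
#' \code{(R*cell + (R+1)*wall + 2*frame, C*cell + (C+1)*wall + 2*frame)}.
#' The frame emulates the non-tissue surround of a real acquisition: in the
#' demo pipeline it forms one large seed region that absorbs the wall ridge
#' network during the watershed and is then removed by the area filter,
#' exactly as over-sized non-cell regions are removed in real analyses. Its
#' intensity sits between the interiors and the wall threshold so the frame
#' basin floods the ridges first.
#'
#' @param rows,cols grid dimensions (positive integers).
#' @param cellSize cell interior side length, pixels.
#' @param wallWidth wall thickness, pixels.
#' @param frameWidth background margin around the outer wall, pixels.
#' @param wallIntensity,interiorIntensity,frameIntensity 8-bit levels.
#' @param noiseSd additive Gaussian noise standard deviation (0 = noise-free).
#' @param zSlices,channels,series,timepoints collection dimensions.
#' @param seed integer RNG seed pinning the noise (byte-reproducibility).
#' @return A validated spec (list of class \code{CellGridSpec}).
#' @examples
#' spec <- cellGridSpec(rows = 3, cols = 3)
#' @export
cellGridSpec <- function(rows = 4L, cols = 5L, cellSize = 50L, wallWidth = 3L,
                         frameWidth = 30L, wallIntensity = 200L,
                         interiorIntensity = 20L, frameIntensity = 40L,
                         noiseSd = 0, zSlices = 3L, channels = 2L,
                         series = 1L, timepoints = 1L, seed = 1L) {
  spec <- list(rows = as.integer(rows), cols = as.integer(cols),
               cellSize = as.integer(cellSize),
               wallWidth = as.integer(wallWidth),
               frameWidth = as.integer(frameWidth),
               wallIntensity = as.integer(wallIntensity),
               interiorIntensity = as.integer(interiorIntensity),
               frameIntensity = as.integer(frameIntensity),
               noiseSd = as.numeric(noiseSd), zSlices = as.integer(zSlices),
               channels = as.integer(channels), series = as.integer(series),
               timepoints = as.integer(timepoints), seed = as.integer(seed))
  with(spec, {
    stopifnot(rows >= 1L, cols >= 1L, wallWidth >= 1L, frameWidth >= 0L,
              noiseSd >= 0, zSlices >= 1L, channels >= 1L, channels <= 2L,
              series >= 1L, timepoints >= 1L,
              wallIntensity > interiorIntensity,
              frameIntensity < wallIntensity)
  })
  if (spec$cellSize <= 4L * spec$wallWidth)
    stop("geometry too small: cellSize must exceed 4 * wallWidth",
         call. = FALSE)
  class(spec) <- "CellGridSpec"
  spec
}

.fixture_shape <- function(spec) {
  c(spec$rows * spec$cellSize + (spec$rows + 1L) * spec$wallWidth +
      2L * spec$frameWidth,
    spec$cols * spec$cellSize + (spec$cols + 1L) * spec$wallWidth +
      2L * spec$frameWidth)
}

# ground-truth labels: interiors 1..R*C in raster order; walls and frame 0
.fixture_truth <- function(spec) {
  shp <- .fixture_shape(spec)
  lab <- matrix(0L, shp[1], shp[2])
  for (i in seq_len(spec$rows)) {
    r0 <- spec$frameWidth + i * spec$wallWidth + (i - 1L) * spec$cellSize + 1L
    for (j in seq_len(spec$cols)) {
      c0 <- spec$frameWidth + j * spec$wallWidth + (j - 1L) * spec$cellSize + 1L
      lab[r0:(r0 + spec$cellSize - 1L), c0:(c0 + spec$cellSize - 1L)] <-
        (i - 1L) * spec$cols + j
    }
  }
  lab
}

# separable Gaussian blur with edge replication
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-rad, rad), sd = sigma)
  k <- k / sum(k)
  blur_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (d in seq(-rad, rad)) {
      idx <- pmin(pmax(seq_len(nrow(m)) + d, 1L), nrow(m))
      out <- out + k[d + rad + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(m))))
}

.clip_uint8 <- function(m) {
  matrix(as.integer(pmin(pmax(round(m), 0), 255)), nrow = nrow(m))
}

# deterministic per-slice noise, isolated from the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.slice_seed <- function(spec, s, c, z, t) {
  (abs(spec$seed) * 7919L + s * 1009L + c * 101L + z * 17L + t * 3L) %%
    2147483647L
}

.render_wall_slice <- function(spec, z) {
  shp <- .fixture_shape(spec)
  zmid <- (spec$zSlices - 1L) %/% 2L
  # small z-dependent modulation of the wall signal (middle slice canonical)
  zfac <- 1 - 0.08 * abs(z - zmid)
  base <- matrix(as.numeric(spec$frameIntensity), shp[1], shp[2])
  grid_r <- (spec$frameWidth + 1L):(shp[1] - spec$frameWidth)
  grid_c <- (spec$frameWidth + 1L):(shp[2] - spec$frameWidth)
  base[grid_r, grid_c] <- spec$wallIntensity * zfac
  truth <- .fixture_truth(spec)
  base[truth > 0L] <- spec$interiorIntensity
  .gauss_blur(base, spec$wallWidth / 4)
}

.render_nuclei_slice <- function(spec, z) {
  shp <- .fixture_shape(spec)
  truth <- .fixture_truth(spec)
  out <- matrix(10, shp[1], shp[2])
  sdn <- spec$cellSize / 6
  rr <- matrix(seq_len(shp[1]), shp[1], shp[2])
  cc <- matrix(seq_len(shp[2]), shp[1], shp[2], byrow = TRUE)
  for (i in seq_len(spec$rows * spec$cols)) {
    idx <- which(truth == i, arr.ind = TRUE)
    cen <- colMeans(idx)
    out <- out + 170 * exp(-((rr - cen[1])^2 + (cc - cen[2])^2) / (2 * sdn^2))
  }
  out
}

.render_slice <- function(spec, s, c, z, t) {
  m <- if (spec$channels >= 2L && c == 0L) .render_nuclei_slice(spec, z)
       else .render_wall_slice(spec, z)
  if (spec$noiseSd > 0) {
    m <- m + .with_seed(.slice_seed(spec, s, c, z, t),
                        matrix(rnorm(length(m), sd = spec$noiseSd),
                               nrow = nrow(m)))
  }
  .clip_uint8(m)
}

#' Generate a synthetic cell-wall image with known ground truth
#'
#' Renders the cell-wall channel of the middle z-slice (by default): bright
#' grid lines over dark interiors inside a background frame, smoothed by a
#' Gaussian of sigma = wallWidth/4 (full width at half maximum about half the
#' wall width -- wide enough to look like optics, narrow enough that
#' thresholding the noise-free image at (wall+interior)/2 recovers the wall
#' grid exactly), plus optional additive Gaussian noise from a generator
#' seeded with \code{spec$seed}, clipped to [0, 255].
#'
#' @param spec a \code{\link{cellGridSpec}}.
#' @param z z-slice to render (default: middle slice).
#' @return List with elements \code{image} (uint8 \linkS4class{ProvImage})
#'   and \code{truth} (\linkS4class{SegmentedImage} labelling the R*C cell
#'   interiors 1..R*C in raster order; walls and frame are background).
#' @examples
#' fx <- generateCellGrid(cellGridSpec(rows = 3, cols = 3, cellSize = 15,
#'                                     wallWidth = 2, frameWidth = 6))
#' identifiers(fx$truth)
#' @export
generateCellGrid <- function(spec, z = NULL) {
  stopifnot(inherits(spec, "CellGridSpec"))
  if (is.null(z)) z <- (spec$zSlices - 1L) %/% 2L
  wall_channel <- if (spec$channels >= 2L) 1L else 0L
  m <- .render_slice(spec, 0L, wall_channel, as.integer(z), 0L)
  img <- imageFromArray(m, sprintf(
    "synthetic cell grid %dx%d (cell %d, wall %d, frame %d, noise %g, seed %d, z %d)",
    spec$rows, spec$cols, spec$cellSize, spec$wallWidth, spec$frameWidth,
    spec$noiseSd, spec$seed, as.integer(z)), dtype = "uint8")
  truth <- SegmentedImage(.fixture_truth(spec),
                          ImageHistory("synthetic ground truth"))
  list(image = img, truth = truth)
}

#' Write a synthetic fixture as a slice collection
#'
#' Writes one grayscale 8-bit TIFF per (series, channel, z, time) coordinate
#' using the \code{S{s}_C{c}_Z{z}_T{t}.tif} naming scheme, plus a JSON
#' manifest (\code{manifest.json}) recording the spec and the per-cell
#' ground-truth centroids and areas. With two channels, channel 1 carries the
#' cell-wall grid (with a small z-dependent intensity modulation) and channel
#' 0 one nuclear blob per cell.
#'
#' @param spec a \code{\link{cellGridSpec}}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a data.frame manifest of the written slice files.
#' @export
generateCollection <- function(spec, outdir) {
  stopifnot(inherits(spec, "CellGridSpec"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  rows <- expand.grid(t = seq_len(spec$timepoints) - 1L,
                      z = seq_len(spec$zSlices) - 1L,
                      c = seq_len(spec$channels) - 1L,
                      s = seq_len(spec$series) - 1L)
  paths <- character(nrow(rows))
  for (k in seq_len(nrow(rows))) {
    co <- rows[k, ]
    m <- .render_slice(spec, co$s, co$c, co$z, co$t)
    f <- file.path(outdir, formatSliceFilename(co$s, co$c, co$z, co$t))
    tiff::writeTIFF(m / 255, f, bits.per.sample = 8L, compression = "none")
    paths[k] <- f
  }
  truth <- .fixture_truth(spec)
  cells <- lapply(seq_len(spec$rows * spec$cols), function(i) {
    idx <- which(truth == i, arr.ind = TRUE)
    list(identifier = i, area = nrow(idx),
         centroid = unname(colMeans(idx)))
  })
  manifest <- list(spec = unclass(spec), cells = cells)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(data.frame(rows[, c("s", "c", "z", "t")], path = paths,
                       stringsAsFactors = FALSE))
}
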