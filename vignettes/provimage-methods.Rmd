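---
title: "provimage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{provimage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative bioimage analysis has a reproducibility problem that is
organisational rather than algorithmic: a finished figure rarely carries a
machine-readable record of the operations that produced it, and the
intermediate images that would let a reader audit each step are usually never
saved. provimage makes both automatic. Every image carries a *history* — a
creation record naming its source plus one event per transformation — and
every transformation routed through the audit decorator writes a numbered PNG
snapshot (`1_threshold_abs.png`, `2_dilate_binary.png`, ...) to disk. A
segmentation workflow therefore leaves, as a side effect, both a textual
audit log and a visual one.

The package has four loosely coupled layers:

* **image core** — `ProvImage` (2D pixels + history), `Stack3D`, PNG
  encoding;
* **data manager** — unpacking multi-dimensional microscopy files into a
  content-addressed cache of 2D TIFF slices, exposed as a
  `MicroscopyCollection` addressable by `(series, channel, z, time)`;
* **transform/segment** — the `transformation()` decorator, binary
  morphology, connected components, seeded watershed, `SegmentedImage` and
  `Region`;
* **annotate** — an RGB canvas with region outlines, crosses, bitmap-font
  text, and a deterministic false-colour scheme.

```{r, eval = FALSE}
library(provimage)
col <- loadCollection("fixture_dir", converter = "tifdir")
wall <- getImage(col, c = 1, z = 1)
seeds <- threshold_abs(wall, 50)
seeds <- dilate_binary(seeds)
seeds <- invert(seeds)
seeds <- remove_small_objects(seeds, min_size = 500)
seeds <- connected_components(seeds, background = 0)
cells <- watershed_with_seeds(-wall, seeds = seeds)
events(cells)
```

## History model

A history is deliberately just strings: a single creation record (set once at
construction) and an append-only vector of call-style events such as
`threshold_abs(image, 50)`. String form makes histories trivially
serialisable and comparable; there is no hidden state to lose. The decorator
renders image-valued arguments as the literal token `image` (their pixel
content is huge and their own provenance is already part of the chain),
positional scalars verbatim, and keyword arguments as `name=value`.

**Which argument donates the history?** The first argument that *carries* a
history (a `ProvImage` or `SegmentedImage`). Bare matrices carry none. This
matters for the watershed idiom `watershed_with_seeds(-wall, seeds = seeds)`:
unary minus on a `ProvImage` intentionally returns a plain signed matrix
(unsigned storage is promoted first, so negation cannot underflow), and the
history is therefore donated by `seeds` — the provenance chain of the final
segmentation runs through the entire seed-construction pipeline back to the
source slice file, which is what a reader auditing the segmentation wants.
Had the landscape donated, the chain would contain a single event.

A transformation called on a bare matrix starts a fresh history with creation
record `created by <name>`; this is a convenience so third-party arrays can
enter a pipeline without ceremony.

## Audit snapshots

One package-global counter is shared by all decorated functions, so a
pipeline's files sort in call order regardless of which module a step came
from. Filenames are `{counter}_{name}.png` with no zero padding. The counter
is resettable (`resetAudit()`), the destination configurable
(`auditDirectory()`), and writing can be disabled (`auditEnabled(FALSE)`)
without affecting history recording. Boolean images encode as 0/255, 8-bit
images pass through, and 16-bit/float images are min-max rescaled to 0..255
with round-half-up (a constant image encodes as all zeros) so audit images
are always viewable; the rounding rule is pinned by tests.
`SegmentedImage` results are written with the false-colour encoding instead,
so segmentation steps appear as colour panels.

## Pinned numerical choices

Several conventions that other libraries leave implementation-defined are
pinned here, because every downstream result depends on them:

* **Coordinates** are (row, col), **1-based**, the native R convention.
* **Structuring element**: all erosion/dilation (the binary transforms,
  `inner`, `border`, `dilate` on regions) uses the 3x3 cross, with image
  borders treated as padded FALSE. Sharing one element keeps chains like
  `dilate(border(inner(r)))` internally consistent.
* **Connected components** use 8-connectivity; labels are consecutive
  1..K assigned in raster (row-major) order of each component's first pixel.
  `connected_components` accepts binary *or* labelled input and groups
  equal-valued pixels, excluding the background value.
* **Watershed** is a priority flood: seed pixels enter a queue in raster
  order; the queue pops by (landscape value, insertion sequence); a pixel is
  labelled the moment it is first queued, and growth is 4-connected. On flat
  terrain this degenerates to multi-source BFS, i.e. nearest seed in the
  Manhattan metric — the property the test oracle checks. FIFO tie-breaking
  on plateaus makes output bit-reproducible across runs and platforms. There
  are no watershed-line pixels: with no mask, every pixel gets a seed label.
* **Perimeter** is the border-pixel count (area of `border(x)`).
  Crack-length and weighted-contour definitions exist; this one is pinned
  and asserted by tests.
* **Convex hull**: the hull polygon is taken over the unit-square corners of
  the member pixels and a pixel joins when its centre lies in the polygon;
  this pass is iterated to its fixed point, so the operator is exactly
  idempotent (a discrete convex closure). One pass alone is not idempotent —
  newly included pixels contribute corners slightly outside the previous
  polygon — which is why the closure, not the single pass, is exposed.
* **Colours**: `pretty_color_from_identifier(i)` seeds a linear congruential
  generator (modulus 2^32, multiplier 1664525, increment 1013904223) with
  `i`, draws three values, and maps each to [63, 255] via `v mod 193 + 63`.
  No platform RNG is involved; the floor keeps segments visible on black.
* **Text** is drawn with an embedded 5x7 bitmap font (digits, A-Z, lowercase
  as uppercase, space; unsupported characters become a hollow box with a
  warning). System font rendering would break byte-determinism across
  platforms. Drawing clips silently at canvas edges so centroid-anchored
  labels near borders cannot error.
* **remove_small_objects** retains components with area >= `min_size`
  (strict removal below the bound).

## The slice cache

Native microscopy formats are unpacked once into
`<backend_root>/<md5-of-input-bytes>/S{s}_C{c}_Z{z}_T{t}.tif`. Content
addressing (MD5 of the file bytes; for a directory input, MD5 of a manifest
of per-file digests) means the conversion happens exactly once per distinct
input, a warm cache is reused byte-for-byte, and — because every image
fetched from a collection records its cached path, which embeds the hash —
provenance chains from any derived image back to the source bytes. MD5 is
used for addressing only; collision resistance is irrelevant for a local
cache. Two converters are built in: `bfconvert` shells out to the external
Bio-Formats tool for native formats (CZI and friends) and is entirely
optional; `tifdir` treats a directory or zip of already-named slices as
pre-converted, which makes the whole package testable with no Java or
external binaries. Non-conforming filenames in a cache directory are skipped
with a warning rather than failing the load. Coordinate sets are reported as
observed; no dense ranges are inferred for sparse collections. Z-stacks are
materialised in memory on request and require contiguous z coordinates.

## The synthetic fixture

`generateCollection()` writes a synthetic two-channel, multi-z collection
emulating a confocal acquisition of plant tissue: channel 1 is a cell-wall
marker (bright grid lines over dark interiors), channel 0 a nuclear marker
(one Gaussian blob per cell). Ground truth is exact: the R x C cell
interiors, labelled 1..R*C in raster order.

Default geometry (the study conditions used by the tests and the acceptance
script): a 4 x 5 grid, 50 px cell interiors, 3 px walls at intensity 200
over interiors at 20, a 30 px background frame at intensity 40 around the
outer wall, Gaussian smoothing with sigma = wallWidth/4, no noise, 3
z-slices (the wall signal is modulated by 8% per z step away from the middle
slice), 2 channels. With these numbers the demo's published parameter roles
(threshold 50, seed `min_size` 500, area filter 40000) work unchanged.

Two generator choices deserve explanation:

* **The background frame.** A real acquisition has non-tissue regions around
  the cells; the published workflow removes them afterwards as "regions too
  large to be cells". The frame is the fixture's analogue. During seeding it
  becomes one large component; during the flood it is the basin that absorbs
  the wall ridge network; the area filter then removes it, leaving exactly
  the R*C cells. Its intensity (40) sits above the interiors (20) and well
  below the threshold (50) so that, in the priority flood, the frame's
  descent reaches the ridges strictly before any cell basin. On a noise-free
  image the wall crest is a connected equal-valued plateau, and a strict
  (value, insertion-order) flood hands an entire plateau to whichever basin
  reaches it first — so which basin that is must be controlled, not left to
  tie-breaking. Making it the frame means the over-sized region removed by
  the area filter is the non-cell region, every cell keeps a symmetric
  pixel set, and recovered centroids land exactly on the ground-truth
  centroids. (Real, noisy images do not have exact plateaus; there the
  walls are split near their midlines. The fixture's noise-free plateaus are
  the harder case for determinism, which is why they are the default.)
* **Blur width.** The smoothing sigma is a quarter of the wall width (full
  width at half maximum roughly half the wall width). This keeps the wall
  grid exactly recoverable by thresholding at the wall/interior midpoint —
  including at wall junctions, where a wider kernel would push
  diagonally-adjacent outside pixels above the midpoint — while still giving
  the threshold mask soft, optics-like shoulders.

What the fixture does *not* emulate: point-spread anisotropy, shot noise
statistics, intensity attenuation with depth, irregular cell shapes, or
touching tissue boundaries. Passing tests on the fixture therefore
demonstrate the correctness and determinism of the machinery — not that the
default parameters segment any particular real tissue; on real data the
threshold, seed size and area cutoffs are the knobs to retune.

## The demo pipeline

`segmentDemo()` is the end-to-end workflow: threshold the wall channel
(strict `>`), dilate to close wall gaps, invert so interiors become seeds,
drop seeds smaller than `min_size`, label the seeds, and flood the negated
wall image. An undecorated loop then removes every region larger than
`maxArea` (default 40000 px). Outputs: the six numbered audit PNGs,
`annotation.png` (each cell outlined via `dilate(border(inner(region)))` in
its deterministic colour, with its pixel area burned in at the centroid,
white by default), and `cells.tsv` (identifier, area, centroid) — the
machine-readable duplicate of the burned-in numbers, because burned-in text
is untestable. The default z-slice is 31 when present (matching typical
hypocotyl stacks), otherwise the middle available slice.

Problem sizes used by the test suite: the study fixture is the default
4 x 5 grid (a 290 x 345 px image); property suites run 100 random 16 x 16
instances per invariant. The whole suite runs in well under a minute, and
the acceptance script in a few seconds.

## Command line

`inst/scripts/provimage-cli.R` exposes `make-fixture`, `convert` and
`segment-demo` subcommands over the exported `cmd*` functions; a YAML config
file can set `backend_root` and the audit settings. The demo subcommand also
logs each recorded history event at INFO level — log-based history
persistence lives in the CLI so the library itself stays silent.

## Known limitations

* 2D only: z-stacks are handled slice-wise by callers; no 3D segmentation.
* Whole stacks are materialised in memory; no virtual/out-of-core stacks.
* Histories are not embedded in written TIFF/PNG metadata; they live on the
  objects (and in the CLI log).
* No OME metadata extraction; coordinates come from filenames alone.
* The area filter in the demo is a plain global threshold; no topology-aware
  post-processing (merging, hole filling) is provided.
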