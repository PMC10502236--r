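---
title: "Streaming whole-slide image conversion: model, contracts and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming whole-slide image conversion: model, contracts and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsiconvert)
```

## The problem

A whole-slide image is a multi-gigapixel scan of a stained tissue section,
stored as a grid of independently compressed tiles so that viewers can read
any region at random. Archives mix containers — vendor TIFF dialects such
as Aperio SVS, the clinical DICOM whole-slide microscopy object, and
chunked-array stores (OME-NGFF on zarr) — and converting between them is
routine preprocessing for computational pathology. The conversion itself is
a streaming problem: the image does not fit in memory, the source's tile
grid rarely matches the requested output grid, and the physical pixel size
(microns per pixel, MPP) must not be lost on the way, because every
downstream measurement depends on it.

`wsiconvert` targets bright-field 8-bit RGB slides only. That matches the
dominant clinical modality (H&E and IHC stains) and what the DICOM WSI
object supports; fluorescence and multichannel data are out of scope, and
readers reject other sample formats rather than guessing.

## Conversion model

### Coordinates and grids

Pixel coordinates are 0-based with the origin at the top-left; regions are
half-open rectangles `[x0, x1) × [y0, y1)`. These are the raster
conventions of all three containers, so no adapter ever translates
coordinates. In R, tile and region *indices* are 1-based and row-major, and
resolution levels are numbered from 1 (full resolution) upward — the
native indexing convention of the language; the containers' own level-0
naming appears only inside the files.

### The regrid plan

The engine reads regions of one size and writes tiles of another. For an
image of `W × H` pixels, read size `r_w × r_h` and tile size `t_w × t_h`,
`plan_regrid()` computes

* the row-major read grid (a partition of the image: every pixel belongs
  to exactly one read region; right/bottom regions are clipped),
* `deps(t)`: the set of read regions whose rectangle intersects write tile
  `t` — pure rectangle intersection, with no alignment requirement
  between the grids, and
* `last_use(r)`: the last write tile depending on region `r`, which is the
  eviction point for the reorder buffer.

The planner is validated against a brute-force per-pixel mapping (each
pixel independently assigned to its read region and write tile) over an
exhaustive sweep of square image sizes 1–65 and read/write sizes 1–16,
plus randomized non-square cases. Those bounds cover every alignment
pattern (equal, nested, coprime, clipped) at sizes where brute force is
exact and fast; larger sizes only repeat the same residue classes.

### The streaming contract

Conversion follows a multiple-reader/single-writer pattern, specified
behaviourally:

1. up to `workers` region reads may be serviced concurrently (default 6);
2. completed regions enter a reorder buffer of capacity `buffer_cap`
   regions beyond the in-flight reads (default `2 × max |deps(t)|`, and
   at least `max |deps(t)|`, otherwise some tile could never assemble —
   violating this is an error at submission);
3. the writer emits tiles in strict row-major order, blocking until every
   dependency of the next tile is buffered;
4. each region is evicted immediately after its `last_use` tile is
   written.

Reads are dispatched ordered by the first tile that needs them, so the
writer is never starved by a read it has not yet requested. Any schedule
satisfying this contract produces the same output file; the implementation
services reads serially in dispatch order, which is one valid interleaving
(a single worker that never runs ahead). This choice makes the output
trivially a pure function of the source pixels and parameters — the
worker count is declared, instrumented and bounded, but cannot influence
bytes on disk. The instrumentation hook reports the peak number of
buffered regions, and the suite asserts `peak ≤ buffer_cap + workers` in
every configuration.

Edge tiles are padded to full tile size with 255 per channel (white, the
bright-field background); containers require full tiles while the true
extent is recorded in the metadata. The pad value is configurable.

On any failure the partial output is deleted. A half-written tiled TIFF is
indistinguishable from a corrupt slide, and a converter that exits nonzero
while leaving a truncated file behind invites silent data loss downstream.

## Tile codecs

* `raw` and `deflate` (zlib streams, as TIFF Deflate and zarr's `zlib`
  compressor expect) are lossless byte codecs.
* `jpeg` is baseline JFIF via libjpeg with the usual quality parameter
  (default 85). Tiles written into TIFF are self-contained streams — the
  shared `JPEGTables` construction is deliberately not written because
  DICOM frames must be self-contained and self-contained streams make the
  transcode byte-identity contract apply to whole streams. Abbreviated
  JPEG-in-TIFF *inputs* are handled by merging the tables into each tile
  stream at read time.
* `jpeg2000` is a JPEG 2000 codestream via openjpeg, always encoded
  reversibly (5/3 wavelet). Lossless J2K is what makes a bit-exact
  conversion chain through DICOM possible at all, since the DICOM WSI
  object does not take uncompressed tiles here.

Supported codec/container pairs: TIFF/SVS take all four; NGFF takes raw,
deflate and jpeg; DICOM takes jpeg and jpeg2000 (transfer syntaxes
1.2.840.10008.1.2.4.50 and .90).

## Transcode mode

When the source already stores JPEG or JPEG 2000 tiles, conversion to a
container that accepts that codec needs no pixel work: streams are copied
byte-for-byte (`run_transcode()`), after a cheap signature check (SOI/EOI
markers for JFIF, SOC or JP2-box signature for J2K) that catches truncated
tiles. Tile size and codec carry over unchanged — retiling is impossible
without decoding. The package counts every pixel decode; on the transcode
path the counter must stay at zero, and the test suite asserts it. The
only exception is an SVS *target*, whose thumbnail must be rendered from
pixels; the thumbnail is regenerated rather than copied because a source
thumbnail may not exist, may be stale, and its dimensions need not match
the requested bound.

The decision matrix (`can_transcode()`): tiff/svs ↔ dicom both codecs,
into ngff jpeg only (the store has no standard J2K chunk codec). NGFF
output with the `jpeg` chunk compressor is this package's own dialect —
the chunks are plain JFIF streams and the `.zarray` records
`{"id": "jpeg"}` — readable by the package itself; raw and zlib NGFF
output is standard zarr v2 readable by any zarr implementation (verified
against python-zarr in the tests).

## Metadata translation

MPP is carried as an exact translation between dialects:

| dialect | representation |
|---|---|
| TIFF | `XResolution`/`YResolution` rationals, unit centimetre: `10^4 / mpp` px/cm |
| SVS | `MPP = <float>` (and `AppMag = <int>`) in the pipe-delimited `ImageDescription` |
| DICOM | `PixelSpacing` in mm, row (y) spacing first, in `PixelMeasuresSequence` |
| NGFF | multiscales coordinate `scale` `[1, mpp_y·d, mpp_x·d]` with axis unit micrometre |

The TIFF rational is built as `10^10 / (mpp·10^6)` reduced by the GCD,
which is exact for any MPP with at most six decimals (all practical
scanner values); otherwise a bounded best rational keeps the relative
error below 1e-9. Acceptance asserts conservation within 1e-6 relative
over all 16 ordered format pairs and chains of three conversions. Unknown
resolution propagates as unknown — no dialect ever receives an invented
1 µm/px default — and the objective power is carried when present but
never synthesised from MPP. The SVS description string emitted here
(`Aperio wsiconvert|AppMag = …|MPP = …`) is a minimal self-consistent
instance of the dialect: its parser and emitter are exact inverses, which
is what the round-trip guarantee actually needs.

## Pyramids and thumbnails

Reduced levels use a separable 2×2 box (area-mean) filter: streaming
friendly, separable, and the standard choice for pathology pyramids, where
high-frequency ringing from sharper kernels has no diagnostic value at
overview magnifications. Edge blocks (1×2, 2×1, 1×1) average only the
pixels present, so level dimensions follow `ceil(dims / factor)` exactly.
Rounding is fixed as half-up to keep outputs platform-deterministic
(`round()`'s banker's rounding is not). Iterated halving differs from
direct `2^k` pooling only through intermediate rounding; an exhaustive 8×8
oracle bounds the difference at ±1 per channel, and that bound is asserted
on full pyramids.

Factors must chain by powers of two (e.g. `c(2, 4, 16)`), because levels
are built by iterated halving of the previous stored level — each level
is streamed tile-by-tile from the one before it, so at no point is more
than one read block held. Source pyramid levels are never copied: archives
contain stale and corrupt reduced levels, and recomputation from level 0
is cheap relative to the conversion itself.

SVS thumbnails reduce level 0 to a longest edge of `thumbnail_max`
(default 1024 px): iterated halving while the halved longest edge still
meets the bound, then one area-mean resize (interval-overlap weights) for
the residual factor below 2.

## The synthetic generator

All tests run against generated slides whose pixel values follow a closed
form: `R = (7x + 13y) mod 256` (smooth ramp), `G = (x XOR y) mod 256`
(high-frequency), `B = 255·(((x div 64) + (y div 64)) mod 2)` (64-px
checkerboard). The mix is chosen adversarially: a smooth channel alone
would hide off-by-one shifts under JPEG loss, the XOR channel breaks any
cancellation between transpose and shift errors, and the checkerboard
catches tile-order mistakes. Because every pixel is a pure function of its
coordinates, any region of any output is verifiable without reference
files.

What the generator does *not* emulate: tissue texture and stain
statistics, sparse background, vendor metadata beyond MPP/magnification,
multi-gigapixel scale, and decoder quirks of other producers' files. The
passing suite therefore demonstrates the correctness of the conversion
machinery — grids, buffering, codecs, containers, metadata — on
standards-conformant input, not robustness to every malformed slide in
the wild. Interoperability is cross-checked in the tests against
independent implementations (python `tifffile`, `zarr`, `pydicom`) rather
than only against this package's own readers.

Test problem sizes are deliberate: the conversion matrix and pyramid laws
run at 2048 × 1536 (12 tiles of 512 px — big enough that edge tiles,
multi-region dependencies and level chains all occur; small enough to
keep the full 16-pair matrix exact-comparison cheap), the transcode
timing comparison at 4096 × 4096, and planner verification sweeps sizes
1–65 exhaustively.

## Known limitations

* Bright-field 8-bit RGB only; other bit depths and channel counts are
  rejected at open time.
* TIFF reading supports tiled layouts without predictors; strip-based
  TIFFs are rejected with a distinct error (an untiled multi-gigapixel
  image cannot be streamed tile-wise anyway).
* DICOM support is single-file, explicit-VR little endian, `TILED_FULL`,
  one fragment per frame — exactly the profile the writer produces, plus
  conformant files from mainstream writers; sparse tiling and
  concatenations are out of scope.
* JP2 as a *container* is not read or written; JPEG 2000 as a *tile codec*
  inside TIFF/DICOM is fully supported.
* Pyramid levels cannot be appended to DICOM outputs (per-level objects
  would be separate files).
* The engine's parallelism is contractual, not mechanical: scheduling is
  deterministic and serial in-process. On the machines this targets the
  pipeline is codec-bound in compiled code; the contract (and its
  instrumentation) is what the format guarantees depend on.
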