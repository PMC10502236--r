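# wsiconvert

Streaming conversion of whole-slide images (WSIs) between tiled container
formats, in R.

Digital pathology archives are heterogeneous collections of multi-gigapixel
scans in vendor TIFF dialects (e.g. Aperio SVS), the clinical DICOM
whole-slide microscopy object, and the cloud-friendly OME-NGFF (zarr)
layout. Converting between them is awkward precisely because the images do
not fit in memory: a converter must stream tiles through a bounded buffer
while the read-side grid and the write-side grid disagree. `wsiconvert`
implements that pipeline for bright-field 8-bit RGB slides:

* **Containers** — tiled TIFF (classic and BigTIFF), the SVS dialect
  (Aperio-style `ImageDescription`, thumbnail IFD), OME-NGFF v0.4
  directory stores, and DICOM WSI (TILED_FULL, encapsulated frames), each
  behind a uniform `open_source()` / `open_sink()` contract. Format
  detection is by content, never by file extension.
* **Tile codecs** — `raw`, `deflate` (zlib), baseline JPEG, and reversible
  (lossless) JPEG 2000, the latter two via bundled libjpeg/openjpeg
  bindings.
* **Regridding engine** — a multiple-reader/single-writer design: read
  regions of one size are buffered, reassembled onto the write-tile grid
  (`plan_regrid()`), and written strictly row-major. The read size, worker
  count and buffer schedule never affect the output bytes. For each write
  tile *t* the planner records `deps(t)`, the set of read regions
  intersecting it, and evicts each region immediately after its last
  dependent tile (`last_use`), so the buffer stays bounded.
* **Transcode mode** — when source tiles are already JPEG/JPEG 2000
  streams, they are repackaged into the target container byte-for-byte with
  zero pixel decodes (`transcode_slide()`), which is one to two orders of
  magnitude faster than re-encoding.
* **Metadata** — microns-per-pixel survives every conversion losslessly:
  TIFF resolution rationals (px/cm), SVS `MPP = …` description fields,
  DICOM `PixelSpacing` (mm, row-first), and NGFF coordinate `scale`
  transforms (µm) are exact translations of each other.
* **Pyramids** — reduced levels by chained 2× box-filter (area-mean)
  downsampling with half-up rounding, appended to a finalized output
  (`append_levels()`); SVS outputs get an aspect-preserving thumbnail.

Everything is testable without reference slides: `generate_fixture()`
writes synthetic slides whose pixel values follow a closed form
(`oracle_pixel(x, y)`), so any region of any output can be verified
independently.

## Worked example

```r
library(wsiconvert)

# a synthetic 2048 x 1536 slide at 0.25 um/px, deflate-tiled TIFF
generate_fixture("slide.tiff", "tiff", width = 2048, height = 1536,
                 tile = 256, codec = "deflate", mpp = 0.25)

# convert to an OME-NGFF store with 512 px tiles and a 3-level pyramid
report <- convert_slide("slide.tiff", "slide.zarr", tile_width = 512,
                        downsample = c(2, 4))
print(report)
#> <wsi_conversion_report> mode convert: 12 tiles, 3.146 megapixels -> slide.zarr
#>   read 512 x 512, workers 6, buffer cap 2, peak buffered regions 1

src <- open_source("slide.zarr")
print(src)
#> <wsi_source:ngff> slide.zarr
#> <wsi_geometry> 2048 x 1536 px, RGB 8-bit, tiles 512 x 512 (4 x 3 grid)
#> <wsi_resolution> 0.25 x 0.25 um/px
#>   codec deflate, 3 level(s)

# pixels round-trip exactly against the closed-form oracle
identical(read_region(src, region(0, 0, 2048, 1536)),
          oracle_block(region(0, 0, 2048, 1536)))
#> [1] TRUE
```

The report says 12 write tiles (the 4 × 3 grid of 512-px tiles) were
produced from 3.1 megapixels, and that the reorder buffer never held more
than one read region — reads and writes were grid-aligned here. With a
mismatched read size (say `read_w = 300`) the peak rises but stays within
the configured capacity.

A transcode repackages JPEG tiles without touching them:

```r
generate_fixture("jslide.tiff", "tiff", codec = "jpeg", mpp = 0.25)
transcode_slide("jslide.tiff", "jslide.dcm", seed = 1)
decode_count()   # pixel decodes on the transcode path
#> [1] 0
```

A command-line wrapper with the same behaviour ships in `inst/cli/`:

```sh
Rscript inst/cli/wsiconvert convert -i slide.tiff -o slide.zarr \
    --tile-size 512 512 --workers 6 --downsample 2 4
Rscript inst/cli/wsiconvert transcode -i jslide.tiff -o jslide.dcm
```

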