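Package: wsiconvert
Title: Streaming Conversion of Whole-Slide Images Between Tiled Container Formats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts multi-gigapixel bright-field whole-slide images between
    tiled container formats (tiled TIFF and its SVS dialect, OME-NGFF v0.4
    directory stores, and DICOM whole-slide microscopy) using a bounded-memory
    multiple-reader/single-writer streaming engine. A regridding planner lets
    the read region size differ from the written tile size; a transcode mode
    repackages already-encoded JPEG or JPEG 2000 tiles into a new container
    without decoding; microns-per-pixel resolution metadata is translated
    losslessly between the container dialects. Includes deterministic synthetic
    slide generation with a closed-form pixel oracle, pyramid level generation
    by box-filter downsampling, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
SystemRequirements: libjpeg, libopenjp2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
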