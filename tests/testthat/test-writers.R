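# The streaming tile-write contract and container finalization.

test_that("codec/format pairs are validated at open time", {
  td <- withr::local_tempdir()
  g <- image_geometry(256, 256, 128)
  err <- tryCatch(open_sink(file.path(td, "x.dcm"), "dicom", g, codec = "raw"),
                  error = function(e) e)
  expect_s3_class(err, "wsi_invalid_parameter")
  expect_match(conditionMessage(err), "jpeg")  # lists the allowed codecs
  expect_wsi_error(open_sink(file.path(td, "x.zarr"), "ngff", g,
                             codec = "jpeg2000"), "invalid_parameter")
  # per-format grids come from ceil division
  s <- open_sink(file.path(td, "ok.tiff"), "tiff",
                 image_geometry(2048, 1536, 512), codec = "deflate")
  expect_equal(s$n_tiles, 12)
  expect_wsi_error(open_sink(file.path(td, "ok.tiff"), "tiff", g),
                   "invalid_parameter")  # refuses to clobber
})

test_that("tiles must be written in row-major order at full size", {
  td <- withr::local_tempdir()
  s <- open_sink(file.path(td, "seq.tiff"), "tiff",
                 image_geometry(256, 256, 128), codec = "raw")
  tile <- array(0L, dim = c(128, 128, 3))
  write_tile(s, 1L, tile)
  expect_wsi_error(write_tile(s, 3L, tile), "sequencing_error")
  expect_wsi_error(write_tile(s, 2L, array(0L, dim = c(64, 128, 3))),
                   "shape_error")
  expect_wsi_error(finalize(s), "incomplete_output")
  err <- tryCatch(finalize(s), error = function(e) e)
  expect_match(conditionMessage(err), "2, 3, 4")  # names the missing tiles
})

test_that("write/read round-trips are exact for every lossless format pair", {
  td <- withr::local_tempdir()
  reg <- region(0, 0, 300, 200)
  src_px <- oracle_block(reg)
  for (tile in c(256L, 512L)) {
    for (fmt in c("tiff", "svs", "ngff", "dicom")) {
      codec <- if (fmt == "dicom") "jpeg2000" else "deflate"
      p <- file.path(td, sprintf("rt_%s_%d", fmt, tile))
      sink <- open_sink(p, fmt, image_geometry(300, 200, tile),
                        resolution = resolution_info(0.25), codec = codec,
                        seed = 6)
      synth <- synthetic_source(300, 200, tile)
      run_conversion(synth, sink, workers = 1)
      expect_identical(read_region(open_source(p), reg), src_px,
                       info = sprintf("%s tile %d", fmt, tile))
    }
  }
})

test_that("JPEG writes keep smooth content within the measured loss bound", {
  td <- withr::local_tempdir()
  p <- file.path(td, "q.tiff")
  sink <- open_sink(p, "tiff", image_geometry(128, 96, 128, 96),
                    codec = "jpeg", quality = 85)
  px <- gradient_block(128, 96)
  pad <- array(255L, dim = c(96, 128, 3))
  pad[1:96, 1:128, ] <- px
  write_tile(sink, 1L, pad)
  finalize(sink)
  back <- read_region(open_source(p), region(0, 0, 128, 96))
  expect_lte(max(abs(back - px)), 30)
})

test_that("encoded tiles are stored byte-for-byte", {
  td <- withr::local_tempdir()
  p <- file.path(td, "e.tiff")
  generate_fixture(p, "tiff", 512, 256, tile = 256, codec = "jpeg")
  tiles <- collect_encoded_tiles(open_source(p))

  out <- file.path(td, "e.dcm")
  sink <- open_sink(out, "dicom", image_geometry(512, 256, 256),
                    resolution = resolution_info(0.5), codec = "jpeg",
                    seed = 8)
  for (i in seq_along(tiles)) write_encoded_tile(sink, i, tiles[[i]])
  finalize(sink)
  back <- collect_encoded_tiles(open_source(out))
  expect_identical(lapply(back, `[[`, "stream"),
                   lapply(tiles, `[[`, "stream"))

  # codec mismatch is a transcode error
  sink2 <- open_sink(file.path(td, "e2.tiff"), "tiff",
                     image_geometry(512, 256, 256), codec = "deflate")
  expect_wsi_error(write_encoded_tile(sink2, 1L, tiles[[1]]),
                   "transcode_unsupported")
})

test_that("finalized outputs re-open with identical geometry and validate", {
  td <- withr::local_tempdir()
  p <- file.path(td, "g.zarr")
  generate_fixture(p, "ngff", 700, 500, tile = 256, codec = "raw", mpp = 1)
  src <- open_source(p)
  expect_equal(src$geometry$width, 700)
  expect_equal(src$geometry$height, 500)
  # NGFF v0.4 multiscales essentials
  attrs <- jsonlite::fromJSON(file.path(p, ".zattrs"), simplifyVector = FALSE)
  ms <- attrs$multiscales[[1]]
  expect_equal(ms$version, "0.4")
  expect_equal(vapply(ms$axes, `[[`, "", "name"), c("c", "y", "x"))
  expect_equal(ms$datasets[[1]]$path, "0")
  expect_length(ms$datasets[[1]]$coordinateTransformations[[1]]$scale, 3)

  # SVS requires its thumbnail before finalize
  sink <- open_sink(file.path(td, "t.svs"), "svs",
                    image_geometry(128, 128, 128), codec = "jpeg")
  write_tile(sink, 1L, array(200L, dim = c(128, 128, 3)))
  expect_wsi_error(finalize(sink), "incomplete_output")
  set_thumbnail(sink, array(200L, dim = c(64, 64, 3)))
  res <- finalize(sink)
  expect_equal(res$tiles_written, 1)
})

test_that("identical runs produce byte-identical files under a fixed seed", {
  td <- withr::local_tempdir()
  for (fmt in c("tiff", "dicom")) {
    p1 <- file.path(td, paste0("d1.", fmt))
    p2 <- file.path(td, paste0("d2.", fmt))
    codec <- if (fmt == "dicom") "jpeg" else "deflate"
    generate_fixture(p1, fmt, 256, 256, tile = 128, codec = codec, seed = 123)
    generate_fixture(p2, fmt, 256, 256, tile = 128, codec = codec, seed = 123)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)), info = fmt)
  }
})
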