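# Format sniffing, the uniform read contract, and encoded-tile iteration.

test_that("format is detected by content and bad inputs are rejected", {
  td <- withr::local_tempdir()
  empty <- file.path(td, "empty.svs")
  file.create(empty)
  expect_wsi_error(open_source(empty), "unsupported_format")

  junk <- file.path(td, "junk.tiff")
  writeBin(as.raw(1:100), junk)
  expect_wsi_error(open_source(junk), "unsupported_format")

  expect_wsi_error(open_source(file.path(td, "missing.tiff")),
                   "invalid_parameter")

  plain_dir <- file.path(td, "notastore")
  dir.create(plain_dir)
  expect_wsi_error(open_source(plain_dir), "unsupported_format")
})

test_that("strip-based TIFFs are rejected with a distinct error", {
  td <- withr::local_tempdir()
  p <- file.path(td, "striped.tif")
  # a legitimate untiled TIFF written by an independent library
  arr <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  tiff::writeTIFF(arr, p)
  err <- tryCatch(open_source(p), error = function(e) e)
  expect_s3_class(err, "wsi_untiled_tiff")
  expect_match(conditionMessage(err), "untiled TIFF not supported")
})

test_that("fixtures read back their geometry and pixels in every format", {
  td <- withr::local_tempdir()
  r_full <- region(0, 0, 600, 400)
  for (f in c("tiff", "ngff", "dicom")) {
    codec <- if (f == "dicom") "jpeg2000" else "deflate"
    p <- file.path(td, paste0("f_", f))
    generate_fixture(p, f, 600, 400, tile = 256, codec = codec, mpp = 0.25,
                     seed = 3)
    src <- open_source(p)
    expect_equal(src$geometry$width, 600)
    expect_equal(src$geometry$height, 400)
    expect_equal(src$geometry$tile_width, 256)
    expect_identical(read_region(src, r_full), oracle_block(r_full),
                     info = f)
    # single pixel, determinism, random sub-regions
    expect_identical(read_region(src, region(0, 0, 1, 1))[1, 1, ],
                     oracle_block(region(0, 0, 1, 1))[1, 1, ])
    set.seed(17)
    for (k in 1:25) {
      x0 <- sample(0:599, 1); y0 <- sample(0:399, 1)
      x1 <- sample((x0 + 1):600, 1); y1 <- sample((y0 + 1):400, 1)
      reg <- region(x0, y0, x1, y1)
      expect_identical(read_region(src, reg), oracle_block(reg))
    }
    expect_identical(read_region(src, region(5, 7, 99, 83)),
                     read_region(src, region(5, 7, 99, 83)))
    expect_wsi_error(read_region(src, region(0, 0, 601, 10)), "bounds_error")
  }
})

test_that("SVS sources expose the dialect metadata and exclude the thumbnail", {
  td <- withr::local_tempdir()
  p <- file.path(td, "s.svs")
  generate_fixture(p, "svs", 600, 400, tile = 256, codec = "jpeg",
                   mpp = 0.4942, objective_power = 20)
  src <- open_source(p)
  expect_equal(src$format, "svs")
  expect_equal(src$resolution$mpp_x, 0.4942)
  expect_equal(src$resolution$objective_power, 20)
  expect_length(src$levels, 1)  # thumbnail IFD is not a level
  expect_true(src$can_yield_encoded_tiles)
})

test_that("encoded tile streams arrive row-major, self-contained, complete", {
  td <- withr::local_tempdir()
  p <- file.path(td, "j.tiff")
  generate_fixture(p, "tiff", 2048, 1536, tile = 256, codec = "jpeg",
                   mpp = 0.25)
  src <- open_source(p)
  tiles <- collect_encoded_tiles(src)
  expect_length(tiles, 48)  # 8 x 6 grid
  for (t in tiles) {
    expect_true(wsiconvert:::jpeg_signature_ok(t$stream))
  }
  expect_equal(vapply(tiles, function(t) t$index, integer(1)), 1:48)

  # DICOM frames come back in the same TILED_FULL order
  pd <- file.path(td, "j.dcm")
  transcode_slide(p, pd, seed = 4)
  dtiles <- collect_encoded_tiles(open_source(pd))
  expect_length(dtiles, 48)
  expect_identical(lapply(dtiles, `[[`, "stream"),
                   lapply(tiles, `[[`, "stream"))

  # byte codecs cannot yield encoded tiles
  p2 <- file.path(td, "d.tiff")
  generate_fixture(p2, "tiff", 256, 256, tile = 128, codec = "deflate")
  expect_wsi_error(iter_encoded_tiles(open_source(p2)), "transcode_unsupported")
})

test_that("python tifffile, zarr and pydicom agree with our containers", {
  td <- withr::local_tempdir()
  generate_fixture(file.path(td, "x.tiff"), "tiff", 320, 256, tile = 128,
                   codec = "deflate", mpp = 0.25)
  generate_fixture(file.path(td, "x.zarr"), "ngff", 320, 256, tile = 128,
                   codec = "deflate", mpp = 0.25)
  generate_fixture(file.path(td, "x.dcm"), "dicom", 320, 256, tile = 128,
                   codec = "jpeg2000", mpp = 0.25, seed = 11)
  script <- sprintf("
import numpy as np, tifffile, zarr, pydicom, sys
x, y = np.meshgrid(np.arange(320), np.arange(256))
oracle = np.stack([(7*x+13*y)%%256, np.bitwise_xor(x,y)%%256,
                   255*(((x//64)+(y//64))%%2)], -1).astype(np.uint8)
a = tifffile.imread(r'%s')
assert np.array_equal(a, oracle), 'tiff pixels'
g = zarr.open_group(r'%s', mode='r')
assert np.array_equal(np.moveaxis(np.asarray(g['0']), 0, -1), oracle), 'zarr pixels'
ds = pydicom.dcmread(r'%s')
assert int(ds.NumberOfFrames) == 6
assert ds.TotalPixelMatrixColumns == 320 and ds.TotalPixelMatrixRows == 256
sp = ds.SharedFunctionalGroupsSequence[0].PixelMeasuresSequence[0].PixelSpacing
assert abs(float(sp[0]) - 0.00025) < 1e-12
print('OK')
", file.path(td, "x.tiff"), file.path(td, "x.zarr"), file.path(td, "x.dcm"))
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("^OK$", out)), info = paste(out, collapse = "\n"))
})
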