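# Microns-per-pixel translation between container dialects.

test_that("TIFF resolution tags convert to microns per pixel", {
  expect_equal(mpp_from_tiff(40000, "centimeter"), 0.25)
  expect_equal(mpp_from_tiff(25400, "inch"), 1.0)
  expect_equal(mpp_from_tiff(10000, "centimeter"), 1.0)
  expect_true(is.na(mpp_from_tiff(40000, "none")))
  expect_true(is.na(mpp_from_tiff(0, "centimeter")))
})

test_that("the emitted TIFF rational round-trips mpp within 1e-9 relative", {
  for (mpp in c(0.25, 0.2525, 0.4942, 1.0, 0.1, 2.5, 1 / 3)) {
    nd <- mpp_to_tiff_rational(mpp)
    recovered <- mpp_from_tiff(nd[1] / nd[2], "centimeter")
    expect_lt(abs(recovered - mpp) / mpp, 1e-9)
    expect_true(all(nd <= 2^32 - 1) && all(nd >= 1))
    expect_true(all(nd == floor(nd)))
  }
})

test_that("DICOM pixel spacing is mm, row (y) first", {
  expect_equal(mpp_to_dicom_pixel_spacing(resolution_info(0.25)),
               c(0.00025, 0.00025))
  expect_equal(mpp_to_dicom_pixel_spacing(resolution_info(0.5, 0.25)),
               c(0.00025, 0.0005))
  expect_equal(mpp_to_dicom_pixel_spacing(resolution_info(1.0)),
               c(0.001, 0.001))
  expect_warning(sp <- mpp_to_dicom_pixel_spacing(resolution_info()),
                 class = "wsi_missing_metadata")
  expect_null(sp)
})

test_that("NGFF scale transforms are (c, y, x) micrometres times downsample", {
  expect_equal(mpp_to_ngff_scale(resolution_info(0.25), 1)$scale, c(1, 0.25, 0.25))
  s <- mpp_to_ngff_scale(resolution_info(0.25), 4)
  expect_equal(s$scale, c(1, 1, 1))
  expect_equal(s$unit, "micrometer")
  unknown <- mpp_to_ngff_scale(resolution_info(), 2)
  expect_equal(unknown$scale, c(1, 1, 1))
  expect_null(unknown$unit)
})

test_that("SVS description strings parse and round-trip", {
  r <- parse_svs_description("Aperio Fake |AppMag = 20|MPP = 0.4942")
  expect_equal(r$mpp_x, 0.4942)
  expect_equal(r$objective_power, 20)

  none <- parse_svs_description("no keys here")
  expect_true(is.na(none$mpp_x))
  expect_null(none$objective_power)

  emitted <- emit_svs_description(resolution_info(0.25, objective_power = 40))
  back <- parse_svs_description(emitted)
  expect_identical(back$mpp_x, 0.25)
  expect_identical(back$objective_power, 40)

  expect_warning(bad <- parse_svs_description("Aperio x|MPP = zero point five"),
                 class = "wsi_malformed_metadata")
  expect_true(is.na(bad$mpp_x))
})

test_that("metadata survives every pairwise conversion within 1e-6 relative", {
  mpp <- 0.2525
  formats <- c("tiff", "svs", "ngff", "dicom")
  td <- withr::local_tempdir()
  paths <- setNames(file.path(td, paste0("m.", formats)), formats)
  for (f in formats) {
    codec <- if (f == "dicom") "jpeg2000" else "deflate"
    generate_fixture(paths[[f]], f, 256, 192, tile = 128, codec = codec,
                     mpp = mpp, seed = 5)
  }
  for (from in formats) {
    for (to in formats) {
      out <- file.path(td, sprintf("x_%s_%s.%s", from, to,
                                   switch(to, tiff = "tiff", svs = "svs",
                                          ngff = "zarr", dicom = "dcm")))
      codec <- if (to == "dicom") "jpeg2000" else "deflate"
      convert_slide(paths[[from]], out, format = to, tile_width = 128,
                    codec = codec, seed = 9)
      got <- open_source(out)$resolution
      expect_lt(abs(got$mpp_x - mpp) / mpp, 1e-6,
                label = sprintf("%s->%s mpp_x rel err", from, to))
      expect_lt(abs(got$mpp_y - mpp) / mpp, 1e-6)
    }
  }
  # a chain of three conversions
  chain1 <- file.path(td, "c1.dcm")
  chain2 <- file.path(td, "c2.zarr")
  chain3 <- file.path(td, "c3.svs")
  convert_slide(paths[["tiff"]], chain1, tile_width = 128, codec = "jpeg2000",
                seed = 2)
  convert_slide(chain1, chain2, tile_width = 128, codec = "deflate")
  convert_slide(chain2, chain3, tile_width = 128, codec = "deflate")
  expect_lt(abs(open_source(chain3)$resolution$mpp_x - mpp) / mpp, 1e-6)
})

test_that("unknown resolution is propagated as unknown, never defaulted", {
  td <- withr::local_tempdir()
  p <- file.path(td, "u.tiff")
  generate_fixture(p, "tiff", 128, 128, tile = 64, codec = "raw", mpp = NULL)
  src <- open_source(p)
  expect_true(is.na(src$resolution$mpp_x))
  out <- file.path(td, "u.zarr")
  convert_slide(p, out, tile_width = 64, codec = "raw")
  expect_true(is.na(open_source(out)$resolution$mpp_x))
})
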