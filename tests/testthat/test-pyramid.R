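# Box-filter downsampling, appended pyramid levels, thumbnails.

test_that("downsample_2x follows the stated mean/rounding/edge rules", {
  expect_equal(downsample_2x(matrix(c(1, 3, 2, 4), 2, 2)),
               matrix(3, 1, 1))  # mean 2.5 rounds half up
  const <- array(255L, dim = c(64, 64, 3))
  lvl <- const
  for (k in 1:3) {
    lvl <- downsample_2x(lvl)
    expect_true(all(lvl == 255L))
  }
  five <- matrix(1:25, 5, 5, byrow = TRUE)
  out <- downsample_2x(five)
  expect_equal(dim(out), c(3L, 3L))
  expect_equal(out[3, 3], five[5, 5])  # 1x1 corner block
  # 1x2 and 2x1 edge blocks average only the pixels present
  expect_equal(out[3, 1], floor(mean(five[5, 1:2]) + 0.5))
  expect_equal(out[1, 3], floor(mean(five[1:2, 5]) + 0.5))
})

test_that("iterated halving matches direct 4x pooling within rounding drift", {
  # exhaustive oracle on small random images: iterated 2x vs direct 4x4
  set.seed(5)
  for (k in 1:20) {
    M <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    twice <- downsample_2x(downsample_2x(M))
    direct <- mean_pool(M, 4)
    expect_lte(max(abs(twice - direct)), 1)
  }
})

test_that("pyramid factors must chain by powers of two", {
  expect_wsi_error(pyramid_spec(3), "invalid_parameter")
  expect_wsi_error(pyramid_spec(c(2, 6)), "invalid_parameter")
  expect_wsi_error(pyramid_spec(c(4, 2)), "invalid_parameter")
  expect_silent(pyramid_spec(c(2, 4, 16)))
})

test_that("appended levels obey the dimension law and the pooling oracle", {
  td <- withr::local_tempdir()
  for (fmt in c("tiff", "ngff")) {
    p <- file.path(td, paste0("p_", fmt))
    generate_fixture(p, fmt, 2048, 1536, tile = 512,
                     codec = "deflate", mpp = 0.25)
    append_levels(p, pyramid_spec(c(2, 4)))
    src <- open_source(p)
    expect_length(src$levels, 3)
    dims <- t(vapply(src$levels, function(l) c(l$geometry$width,
                                               l$geometry$height),
                     numeric(2)))
    expect_equal(dims, rbind(c(2048, 1536), c(1024, 768), c(512, 384)))

    # sampled windows of level 2 match direct 4x4 pooling of level 0 +-1
    lv2 <- read_region(src, region(0, 0, 128, 128), level = 3)
    base <- oracle_block(region(0, 0, 512, 512))
    for (ch in 1:3) {
      expect_lte(max(abs(lv2[, , ch] - mean_pool(base[, , ch], 4))), 1,
                 label = sprintf("%s level2 ch%d", fmt, ch))
    }
    # global mean drift stays within the rounding bound
    lv_all <- read_region(src, region(0, 0, 512, 384), level = 3)
    or_all <- oracle_block(region(0, 0, 2048, 1536))
    expect_lte(abs(mean(lv_all) - mean(or_all)), 1)
  }
  # NGFF multiscales updated with all datasets and scaled transforms
  attrs <- jsonlite::fromJSON(file.path(td, "p_ngff", ".zattrs"),
                              simplifyVector = FALSE)
  ds <- attrs$multiscales[[1]]$datasets
  expect_equal(vapply(ds, `[[`, "", "path"), c("0", "1", "2"))
  expect_equal(ds[[3]]$coordinateTransformations[[1]]$scale[[2]], 1.0)
})

test_that("unchained factors and DICOM targets are rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "x.tiff")
  generate_fixture(p, "tiff", 256, 256, tile = 128, codec = "raw")
  expect_wsi_error(append_levels(p, c(3)), "invalid_parameter")
  d <- file.path(td, "x.dcm")
  generate_fixture(d, "dicom", 256, 256, tile = 128, codec = "jpeg", seed = 1)
  expect_wsi_error(append_levels(d, c(2)), "invalid_parameter")
})

test_that("thumbnails preserve aspect and reduce by area means", {
  src <- synthetic_source(2048, 1536, 512)
  th <- make_thumbnail(src, 1024)
  expect_equal(dim(th), c(768L, 1024L, 3L))
  th2 <- make_thumbnail(src, 500)
  expect_equal(dim(th2), c(375L, 500L, 3L))
  const <- synthetic_source(777, 333, 256, pattern = "constant", value = 128)
  tc <- make_thumbnail(const, 100)
  expect_true(all(tc == 128L))
  expect_equal(dim(tc)[2], 100L)
  small <- synthetic_source(64, 48, 64)
  expect_equal(dim(make_thumbnail(small, 1024)), c(48L, 64L, 3L))
})

test_that("SVS conversions embed a thumbnail IFD", {
  td <- withr::local_tempdir()
  f <- file.path(td, "s0.tiff")
  generate_fixture(f, "tiff", 2048, 1536, tile = 512, codec = "deflate",
                   mpp = 0.25)
  out <- file.path(td, "s.svs")
  convert_slide(f, out, codec = "jpeg", tile_width = 512)
  parsed <- wsiconvert:::tiff_parse(out)
  expect_length(parsed$ifds, 2)
  expect_false(wsiconvert:::tiff_is_tiled(parsed$ifds[[2]]))
  expect_equal(wsiconvert:::tiff_tag(parsed$ifds[[2]], 256), 1024)
  expect_equal(wsiconvert:::tiff_tag(parsed$ifds[[2]], 257), 768)
})
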