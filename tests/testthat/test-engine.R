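# The multiple-reader/single-writer streaming pipeline: determinism,
# dispatch order, bounded buffering, and failure hygiene.

test_that("dispatch order serves the writer's next tile first", {
  # identity plan: natural order
  p1 <- plan_regrid(image_geometry(1024, 1024, 512), 512, 512)
  expect_equal(dispatch_order(p1), 1:4)

  # read 256 / write 512 on 1024x1024: all regions of write tile 1
  # (read grid (0,0), (1,0), (0,1), (1,1)) precede any region exclusive
  # to tile 2
  p2 <- plan_regrid(image_geometry(1024, 1024, 512), 256, 256)
  ord <- dispatch_order(p2)
  tile1_regions <- p2$deps[[1]]
  tile2_only <- setdiff(p2$deps[[2]], tile1_regions)
  expect_true(max(match(tile1_regions, ord)) < min(match(tile2_only, ord)))

  # single read region
  p3 <- plan_regrid(image_geometry(100, 100, 50), 100, 100)
  expect_equal(dispatch_order(p3), 1L)
})

test_that("serial reference run converts exactly and bounds its buffer", {
  td <- withr::local_tempdir()
  f <- file.path(td, "src.tiff")
  generate_fixture(f, "tiff", 2048, 1536, tile = 512, codec = "deflate",
                   mpp = 0.25)
  src <- open_source(f)
  out <- file.path(td, "out.tiff")
  sink <- open_sink(out, "tiff", image_geometry(2048, 1536, 512),
                    src$resolution, codec = "deflate")
  rep <- run_conversion(src, sink, read_w = 512, read_h = 512, workers = 1)
  expect_equal(rep$tiles_written, 12)
  expect_equal(rep$pixels_processed, 2048 * 1536)
  expect_lte(rep$peak_buffered_regions, rep$buffer_cap + 1)
  full <- region(0, 0, 2048, 1536)
  expect_identical(read_region(open_source(out), full), oracle_block(full))
})

test_that("output files are identical across worker counts and read sizes", {
  td <- withr::local_tempdir()
  f <- file.path(td, "src.tiff")
  generate_fixture(f, "tiff", 1000, 700, tile = 256, codec = "deflate",
                   mpp = 0.25)
  src <- open_source(f)
  outs <- character(0)
  for (cfg in list(list(w = 1, r = 512), list(w = 6, r = 512),
                   list(w = 6, r = 256), list(w = 3, r = 300))) {
    out <- file.path(td, sprintf("o_w%d_r%d.dcm", cfg$w, cfg$r))
    sink <- open_sink(out, "dicom", image_geometry(1000, 700, 512),
                      src$resolution, codec = "jpeg2000", seed = 99)
    rep <- run_conversion(src, sink, read_w = cfg$r, read_h = cfg$r,
                          workers = cfg$w)
    expect_lte(rep$peak_buffered_regions, rep$buffer_cap + cfg$w)
    outs <- c(outs, out)
  }
  ref <- readBin(outs[1], "raw", file.size(outs[1]))
  for (o in outs[-1]) {
    expect_identical(readBin(o, "raw", file.size(o)), ref, info = o)
  }
})

test_that("a conversion with an undersized buffer is refused at submit", {
  src <- synthetic_source(512, 512, 128)
  td <- withr::local_tempdir()
  sink <- open_sink(file.path(td, "b.tiff"), "tiff",
                    image_geometry(512, 512, 256), codec = "raw")
  # each 256-tile needs 4 of the 128-regions; cap 3 can never assemble one
  expect_wsi_error(
    run_conversion(src, sink, read_w = 128, read_h = 128, buffer_cap = 3),
    "invalid_parameter")
})

test_that("the writer terminates on a 100-tile grid at minimal buffer", {
  src <- synthetic_source(500, 500, 50)
  td <- withr::local_tempdir()
  out <- file.path(td, "many.tiff")
  sink <- open_sink(out, "tiff", image_geometry(500, 500, 50), codec = "raw")
  plan <- plan_regrid(image_geometry(500, 500, 50), 130, 130)
  max_deps <- max(lengths(plan$deps))
  rep <- run_conversion(src, sink, read_w = 130, read_h = 130,
                        workers = 1, buffer_cap = max_deps)
  expect_equal(rep$tiles_written, 100)
  full <- region(0, 0, 500, 500)
  expect_identical(read_region(open_source(out), full), oracle_block(full))
})

test_that("a failing read aborts the job and removes partial output", {
  td <- withr::local_tempdir()
  src <- synthetic_source(512, 512, 128)
  poisoned <- src
  class(poisoned) <- c("wsi_source_poisoned", class(src))
  assign("read_region.wsi_source_poisoned",
         function(src, reg, level = 1L, ...) {
           if (reg$y0 >= 256) stop("simulated reader failure")
           NextMethod()
         }, envir = globalenv())
  withr::defer(rm("read_region.wsi_source_poisoned", envir = globalenv()))
  registerS3method("read_region", "wsi_source_poisoned",
                   get("read_region.wsi_source_poisoned", envir = globalenv()),
                   envir = globalenv())
  out <- file.path(td, "part.tiff")
  sink <- open_sink(out, "tiff", image_geometry(512, 512, 128), codec = "raw")
  expect_error(run_conversion(poisoned, sink, workers = 1),
               "simulated reader failure")
  expect_false(file.exists(out))
})

test_that("progress logging emits the configured number of lines", {
  src <- synthetic_source(512, 512, 128)
  td <- withr::local_tempdir()
  sink <- open_sink(file.path(td, "p.tiff"), "tiff",
                    image_geometry(512, 512, 128), codec = "raw")
  msgs <- capture_messages(run_conversion(src, sink, workers = 1,
                                          progress = 25))
  expect_length(msgs, 4)
  expect_match(msgs[4], "16/16")
})
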