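# Tile grids, read-grid partitioning, and the regridding planner.

test_that("read grids partition the image exactly, with edge clipping", {
  g <- image_geometry(1024, 1024, 512)
  grid <- make_read_grid(g, 512, 512)
  expect_length(grid, 4)
  expect_true(all(vapply(grid, function(r) (r$x1 - r$x0) == 512 &&
                           (r$y1 - r$y0) == 512, logical(1))))

  g2 <- image_geometry(1000, 700, 512)
  grid2 <- make_read_grid(g2, 512, 512)
  expect_length(grid2, 4)
  corner <- grid2[[4]]  # grid position (1,1), row-major
  expect_equal(c(corner$x0, corner$x1, corner$y0, corner$y1),
               c(512, 1000, 512, 700))

  g3 <- image_geometry(65, 65, 16)
  grid3 <- make_read_grid(g3, 16, 16)
  expect_length(grid3, 25)
  areas <- vapply(grid3, function(r) (r$x1 - r$x0) * (r$y1 - r$y0), numeric(1))
  expect_equal(sum(areas), 4225)

  expect_wsi_error(make_read_grid(g, 0, 16), "invalid_parameter")
})

test_that("plan_regrid matches the stated dependency examples", {
  # identical grids -> identity mapping
  p1 <- plan_regrid(image_geometry(1024, 1024, 512), 512, 512)
  expect_true(all(lengths(p1$deps) == 1))
  expect_equal(unlist(p1$deps), 1:4)

  # one giant read region feeds every tile
  p2 <- plan_regrid(image_geometry(1024, 1024, 256), 1024, 1024)
  expect_length(p2$deps, 16)
  expect_true(all(vapply(p2$deps, identical, logical(1), 1L)))

  # unaligned read size: tile at write grid (1,0) = [256,512)x[0,256)
  # overlaps read-grid columns 0 and 1 of row 0
  p3 <- plan_regrid(image_geometry(1024, 512, 256), 300, 300)
  t_idx <- 2L  # grid (1,0), row-major
  expect_equal(p3$deps[[t_idx]], c(1L, 2L))
})

test_that("planner dependencies equal the per-pixel brute-force mapping", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(1:65, 1)
    r <- sample(1:16, 1)
    t <- sample(1:16, 1)
    plan <- plan_regrid(image_geometry(n, n, t), r, r)
    expect_identical(plan_deps_pairs(plan), brute_force_deps(n, n, r, t),
                     info = sprintf("n=%d read=%d tile=%d", n, r, t))
  }
  # non-square case
  plan <- plan_regrid(image_geometry(37, 53, 7, 9), 11, 5)
  xs <- rep(0:36, times = 53); ys <- rep(0:52, each = 37)
  region_id <- (ys %/% 5) * ceiling(37 / 11) + xs %/% 11 + 1L
  tile_id <- (ys %/% 9) * ceiling(37 / 7) + xs %/% 7 + 1L
  expect_identical(plan_deps_pairs(plan), sort(unique(tile_id * 1e6 + region_id)))
})

test_that("every pixel is claimed by exactly one read region and one tile", {
  for (cfg in list(c(65, 16, 16), c(64, 16, 16), c(1, 1, 1), c(33, 7, 5))) {
    n <- cfg[1]; r <- cfg[2]; t <- cfg[3]
    plan <- plan_regrid(image_geometry(n, n, t), r, r)
    claimed <- matrix(0L, n, n)
    for (reg in plan$read_regions) {
      claimed[(reg$y0 + 1):reg$y1, (reg$x0 + 1):reg$x1] <-
        claimed[(reg$y0 + 1):reg$y1, (reg$x0 + 1):reg$x1] + 1L
    }
    expect_true(all(claimed == 1L), info = paste(cfg, collapse = "/"))
  }
})

test_that("last_use is the maximum dependent tile of each region", {
  plan <- plan_regrid(image_geometry(100, 80, 16), 24, 24)
  for (r in seq_along(plan$read_regions)) {
    dependents <- which(vapply(plan$deps, function(d) r %in% d, logical(1)))
    expect_equal(plan$last_use[r], max(dependents))
  }
})

test_that("assemble_tile copies dependencies and pads the image margin", {
  # interior tile covered by a single larger region: straight copy
  g <- image_geometry(1024, 1024, 256)
  plan <- plan_regrid(g, 1024, 1024)
  full <- oracle_block(region(0, 0, 1024, 1024))
  tile7 <- assemble_tile(plan, 7L, list(`1` = full))
  # tile 7 is grid (2,1): [512,768)x[256,512)
  expect_identical(tile7, oracle_block(region(512, 256, 768, 512)))

  # tile spanning 4 read regions equals the oracle sub-block
  plan2 <- plan_regrid(image_geometry(1024, 1024, 512), 256, 256)
  deps1 <- plan2$deps[[1]]
  blocks <- setNames(lapply(deps1, function(r) {
    oracle_block(plan2$read_regions[[r]])
  }), as.character(deps1))
  expect_identical(assemble_tile(plan2, 1L, blocks),
                   oracle_block(region(0, 0, 512, 512)))

  # edge tile of a 1000x700 image: out-of-bounds area is pad value 255
  g3 <- image_geometry(1000, 700, 512)
  plan3 <- plan_regrid(g3, 512, 512)
  deps4 <- plan3$deps[[4]]
  blocks3 <- setNames(lapply(deps4, function(r) {
    oracle_block(plan3$read_regions[[r]])
  }), as.character(deps4))
  tile4 <- assemble_tile(plan3, 4L, blocks3)
  expect_equal(dim(tile4), c(512L, 512L, 3L))
  expect_identical(tile4[1:188, 1:488, ], oracle_block(region(512, 512, 1000, 700)))
  expect_true(all(tile4[, 489:512, ] == 255L))
  expect_true(all(tile4[189:512, , ] == 255L))

  # configurable pad
  tile4b <- assemble_tile(plan3, 4L, blocks3, pad_value = 0L)
  expect_true(all(tile4b[, 489:512, ] == 0L))

  # missing dependency names the absent region
  expect_error(assemble_tile(plan3, 4L, blocks3[-1]),
               regexp = as.character(deps4[1]),
               class = "wsi_incomplete_dependencies")
})
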