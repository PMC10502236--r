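# Coordinate conventions, tile grids, and the regridding planner.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based with the origin at the top-left;
#   * regions are half-open rectangles [x0, x1) x [y0, y1);
#   * tile and region indices are 1-based and row-major (R convention);
#   * pixel blocks are integer arrays of dim c(height, width, 3), values 0..255.

#' Image geometry of one resolution level
#'
#' Describes the pixel extent and tile layout of a single resolution level of
#' a bright-field RGB whole-slide image. Only 8-bit, 3-channel images are
#' supported; other modalities are rejected by the format readers.
#'
#' @param width,height Image extent in pixels (>= 1).
#' @param tile_width,tile_height Tile extent in pixels (>= 1). Defaults to
#'   512, the conventional normalised output tile size for slide conversion.
#' @return An object of class `wsi_geometry`.
#' @examples
#' g <- image_geometry(2048, 1536, 256)
#' tile_grid_dims(g)  # 8 x 6 tiles
#' @export
image_geometry <- function(width, height, tile_width = 512L,
                           tile_height = tile_width) {
  width <- check_count(width, "width")
  height <- check_count(height, "height")
  tile_width <- check_count(tile_width, "tile_width")
  tile_height <- check_count(tile_height, "tile_height")
  structure(
    list(width = width, height = height, channels = 3L, bitdepth = 8L,
         tile_width = tile_width, tile_height = tile_height),
    class = "wsi_geometry"
  )
}

#' @export
print.wsi_geometry <- function(x, ...) {
  gd <- tile_grid_dims(x)
  cat(sprintf("<wsi_geometry> %d x %d px, RGB 8-bit, tiles %d x %d (%d x %d grid)\n",
              x$width, x$height, x$tile_width, x$tile_height, gd[1], gd[2]))
  invisible(x)
}

#' Tile grid dimensions of a geometry
#'
#' @param geometry A [image_geometry()] object.
#' @return Integer vector `c(nx, ny)`: number of tile columns and rows.
#' @export
tile_grid_dims <- function(geometry) {
  c(ceil_div(geometry$width, geometry$tile_width),
    ceil_div(geometry$height, geometry$tile_height))
}

#' Rectangular pixel region
#'
#' Half-open rectangle `[x0, x1) x [y0, y1)` in 0-based pixel coordinates,
#' origin top-left.
#'
#' @param x0,y0 Inclusive top-left corner.
#' @param x1,y1 Exclusive bottom-right corner.
#' @return An object of class `wsi_region`.
#' @export
region <- function(x0, y0, x1, y1) {
  if (x0 < 0 || y0 < 0 || x1 <= x0 || y1 <= y0) {
    stop_wsi(sprintf("invalid region [%s,%s)x[%s,%s): need 0 <= x0 < x1, 0 <= y0 < y1",
                     x0, x1, y0, y1), "invalid_parameter")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "wsi_region")
}

region_width <- function(r) r$x1 - r$x0
region_height <- function(r) r$y1 - r$y0
region_area <- function(r) as.double(region_width(r)) * region_height(r)

#' @export
print.wsi_region <- function(x, ...) {
  cat(sprintf("<wsi_region> [%d,%d) x [%d,%d)  (%d x %d px)\n",
              x$x0, x$x1, x$y0, x$y1, region_width(x), region_height(x)))
  invisible(x)
}

# Unclipped rectangle of write tile (gx, gy) (0-based grid coords).
tile_rect_unclipped <- function(geometry, gx, gy) {
  list(x0 = gx * geometry$tile_width, y0 = gy * geometry$tile_height,
       x1 = (gx + 1L) * geometry$tile_width,
       y1 = (gy + 1L) * geometry$tile_height)
}

# Rectangle of write tile clipped to image bounds, as a wsi_region.
tile_rect_clipped <- function(geometry, gx, gy) {
  r <- tile_rect_unclipped(geometry, gx, gy)
  region(r$x0, r$y0, min(r$x1, geometry$width), min(r$y1, geometry$height))
}

#' Row-major read-region grid over an image
#'
#' Partitions the image rectangle into regions of size `read_w` x `read_h`,
#' row-major, with the right/bottom-most regions clipped to the image bounds.
#' Every image pixel falls in exactly one region.
#'
#' @param geometry A [image_geometry()] object.
#' @param read_w,read_h Read region size in pixels (>= 1).
#' @return List of [region()] objects in row-major order.
#' @export
make_read_grid <- function(geometry, read_w, read_h) {
  read_w <- check_count(read_w, "read_w")
  read_h <- check_count(read_h, "read_h")
  nx <- ceil_div(geometry$width, read_w)
  ny <- ceil_div(geometry$height, read_h)
  out <- vector("list", nx * ny)
  k <- 1L
  for (gy in 0:(ny - 1L)) {
    for (gx in 0:(nx - 1L)) {
      out[[k]] <- region(gx * read_w, gy * read_h,
                         min((gx + 1L) * read_w, geometry$width),
                         min((gy + 1L) * read_h, geometry$height))
      k <- k + 1L
    }
  }
  out
}

#' Plan the regridding between a read grid and the write-tile grid
#'
#' The streaming engine reads regions of one size and writes tiles of another.
#' The plan records, for every write tile, which read regions intersect it
#' (`deps`), and for every read region, the last write tile that needs it
#' (`last_use`) so the reorder buffer can evict regions as early as possible.
#' Read size need not align with the tile size in any way; dependencies are
#' computed by rectangle intersection.
#'
#' @param geometry A [image_geometry()] object (write tile size is taken from
#'   it).
#' @param read_w,read_h Read region size in pixels.
#' @return An object of class `wsi_regrid_plan` with elements `read_regions`
#'   (row-major list of [region()]), `deps` (list: write tile index ->
#'   integer vector of read region indices), `last_use` (integer vector:
#'   read region index -> last dependent write tile index), `read_grid`
#'   and `write_grid` (`c(nx, ny)` each), and `geometry`.
#' @export
plan_regrid <- function(geometry, read_w, read_h) {
  read_w <- check_count(read_w, "read_w")
  read_h <- check_count(read_h, "read_h")
  read_regions <- make_read_grid(geometry, read_w, read_h)
  nrx <- ceil_div(geometry$width, read_w)
  nry <- ceil_div(geometry$height, read_h)
  wg <- tile_grid_dims(geometry)
  ntx <- wg[1]; nty <- wg[2]

  n_tiles <- ntx * nty
  deps <- vector("list", n_tiles)
  for (gy in 0:(nty - 1L)) {
    for (gx in 0:(ntx - 1L)) {
      t_idx <- gy * ntx + gx + 1L
      rect <- tile_rect_clipped(geometry, gx, gy)
      rc0 <- rect$x0 %/% read_w
      rc1 <- (rect$x1 - 1L) %/% read_w
      rr0 <- rect$y0 %/% read_h
      rr1 <- (rect$y1 - 1L) %/% read_h
      cols <- rc0:rc1
      rows <- rr0:rr1
      deps[[t_idx]] <- sort(as.integer(outer(cols, rows * nrx, "+")) + 1L)
    }
  }

  last_use <- integer(length(read_regions))
  for (t in seq_len(n_tiles)) {
    for (r in deps[[t]]) last_use[r] <- max(last_use[r], t)
  }

  structure(
    list(read_regions = read_regions, deps = deps, last_use = last_use,
         read_grid = c(nrx, nry), write_grid = c(ntx, nty),
         read_w = read_w, read_h = read_h, geometry = geometry),
    class = "wsi_regrid_plan"
  )
}

#' @export
print.wsi_regrid_plan <- function(x, ...) {
  cat(sprintf(paste0("<wsi_regrid_plan> image %d x %d, read %d x %d ",
                     "(%d x %d grid), write %d x %d (%d x %d grid), ",
                     "max deps/tile %d\n"),
              x$geometry$width, x$geometry$height, x$read_w, x$read_h,
              x$read_grid[1], x$read_grid[2],
              x$geometry$tile_width, x$geometry$tile_height,
              x$write_grid[1], x$write_grid[2],
              max(lengths(x$deps))))
  invisible(x)
}

#' Assemble one write tile from buffered read regions
#'
#' Copies the pixels of every dependency region that intersect the tile into
#' a full-size tile block. Pixels beyond the image extent (right/bottom edge
#' tiles) are filled with `pad_value`; containers require full tiles while the
#' true extent is recorded in metadata.
#'
#' @param plan A [plan_regrid()] result.
#' @param tile_index 1-based row-major write tile index.
#' @param region_pixels Named list mapping read region index (as character)
#'   to its pixel block (dim `c(h, w, 3)`, clipped region shape).
#' @param pad_value Fill value for out-of-bounds pixels (default 255, white:
#'   the bright-field background).
#' @return Integer array `c(tile_height, tile_width, 3)`.
#' @export
assemble_tile <- function(plan, tile_index, region_pixels, pad_value = 255L) {
  geometry <- plan$geometry
  n_tiles <- prod(plan$write_grid)
  if (!is_count(tile_index) || tile_index > n_tiles) {
    stop_wsi(sprintf("tile_index must be in 1..%d", n_tiles), "invalid_parameter")
  }
  ntx <- plan$write_grid[1]
  gx <- (tile_index - 1L) %% ntx
  gy <- (tile_index - 1L) %/% ntx
  t_rect <- tile_rect_unclipped(geometry, gx, gy)

  out <- array(as.integer(pad_value),
               dim = c(geometry$tile_height, geometry$tile_width, 3L))
  for (r_idx in plan$deps[[tile_index]]) {
    key <- as.character(r_idx)
    block <- region_pixels[[key]]
    if (is.null(block)) {
      stop_wsi(sprintf("missing pixels for read region %d required by tile %d",
                       r_idx, tile_index), "incomplete_dependencies")
    }
    r <- plan$read_regions[[r_idx]]
    ix0 <- max(r$x0, t_rect$x0); ix1 <- min(r$x1, t_rect$x1)
    iy0 <- max(r$y0, t_rect$y0); iy1 <- min(r$y1, t_rect$y1)
    if (ix0 >= ix1 || iy0 >= iy1) next
    out[(iy0 - t_rect$y0 + 1L):(iy1 - t_rect$y0),
        (ix0 - t_rect$x0 + 1L):(ix1 - t_rect$x0), ] <-
      block[(iy0 - r$y0 + 1L):(iy1 - r$y0),
            (ix0 - r$x0 + 1L):(ix1 - r$x0), , drop = FALSE]
  }
  out
}
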