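# Format adapters exposing a uniform random-access region-read contract over
# tiled TIFF/SVS, NGFF v0.4 stores, and DICOM WSI files. Format detection is
# by content, never by extension: SVS is a TIFF dialect and extensions are
# unreliable in the wild.

#' Open a slide for reading
#'
#' Sniffs the container format by content (TIFF magic bytes, a `DICM` marker
#' at offset 128, or the presence of zarr group metadata in a directory) and
#' returns a slide source exposing a uniform read contract. Only 8-bit,
#' 3-channel bright-field images are accepted; strip-based (untiled) TIFFs
#' are rejected with a distinct error.
#'
#' @param path File (TIFF/SVS/DICOM) or directory (NGFF store).
#' @return An object of class `wsi_source` with fields `geometry` (level 1),
#'   `resolution`, `levels` (list of `list(downsample, geometry)` with
#'   strictly increasing downsample factors), `codec`, and
#'   `can_yield_encoded_tiles`.
#' @seealso [read_region()], [iter_encoded_tiles()], [open_sink()]
#' @export
open_source <- function(path) {
  if (dir.exists(path)) {
    if (ngff_is_store(path)) return(open_source_ngff(path))
    stop_wsi(sprintf("'%s' is a directory but not an NGFF store", path),
             "unsupported_format")
  }
  if (!file.exists(path)) {
    stop_wsi(sprintf("'%s' does not exist", path), "invalid_parameter")
  }
  sz <- file.size(path)
  head <- readBin(path, "raw", min(sz, 4L))
  if (length(head) >= 4 &&
      (identical(head[1:2], charToRaw("II")) ||
         identical(head[1:2], charToRaw("MM")))) {
    magic <- raw_to_int(head[3:4], 2,
                        if (head[1] == as.raw(0x49)) "little" else "big")
    if (magic %in% c(42, 43)) return(open_source_tiff(path))
  }
  if (dicom_is_file(path)) return(open_source_dicom(path))
  stop_wsi(sprintf("'%s': unknown or unsupported image format", path),
           "unsupported_format")
}

#' Read a pixel region from a slide
#'
#' A pure function of `(source, region, level)`: repeated and concurrent
#' calls return identical blocks. The region must lie fully within the level
#' bounds; the engine always requests in-bounds clipped regions.
#'
#' @param src A source from [open_source()] or [synthetic_source()].
#' @param reg A [region()] in the coordinate system of `level`.
#' @param level 1-based resolution level (1 = full resolution).
#' @param ... Adapter-specific arguments (unused).
#' @return Integer pixel array `c(height, width, 3)`, values 0..255.
#' @export
read_region <- function(src, reg, level = 1L, ...) UseMethod("read_region")

#' Stream the stored encoded tiles of a slide
#'
#' For sources whose tiles are stored as JPEG or JPEG 2000 streams, yields
#' the stored tile streams in row-major order without decoding them. Streams
#' are always self-contained: abbreviated JPEG-in-TIFF tiles (shared
#' JPEGTables tag) have the tables merged in before they are yielded.
#'
#' @param src A source from [open_source()].
#' @param level 1-based resolution level.
#' @return A list with `n` (tile count) and `next_tile()`, a closure
#'   returning the next [encoded_tile()] or `NULL` when exhausted.
#' @export
iter_encoded_tiles <- function(src, level = 1L) UseMethod("iter_encoded_tiles")

#' Collect all encoded tiles into a list
#'
#' Convenience wrapper around [iter_encoded_tiles()] for small images.
#'
#' @inheritParams iter_encoded_tiles
#' @return List of [encoded_tile()] in row-major order.
#' @export
collect_encoded_tiles <- function(src, level = 1L) {
  it <- iter_encoded_tiles(src, level)
  out <- vector("list", it$n)
  for (i in seq_len(it$n)) out[[i]] <- it$next_tile()
  out
}

#' @export
iter_encoded_tiles.default <- function(src, level = 1L) {
  stop_wsi(sprintf("%s sources cannot yield encoded tiles (codec '%s')",
                   src$format, src$codec), "transcode_unsupported")
}

#' @export
print.wsi_source <- function(x, ...) {
  cat(sprintf("<wsi_source:%s> %s\n", x$format,
              if (is.na(x$path)) "<in memory>" else x$path))
  print(x$geometry)
  print(x$resolution)
  cat(sprintf("  codec %s, %d level(s)%s\n", x$codec, length(x$levels),
              if (x$can_yield_encoded_tiles) ", encoded tiles available" else ""))
  invisible(x)
}

check_region_bounds <- function(src, reg, level) {
  if (level < 1 || level > length(src$levels)) {
    stop_wsi(sprintf("level %s out of range 1..%d", level, length(src$levels)),
             "bounds_error")
  }
  g <- src$levels[[level]]$geometry
  if (reg$x1 > g$width || reg$y1 > g$height) {
    stop_wsi(sprintf("region [%d,%d)x[%d,%d) exceeds level %d bounds %d x %d",
                     reg$x0, reg$x1, reg$y0, reg$y1, level, g$width, g$height),
             "bounds_error")
  }
  invisible(TRUE)
}

check_rgb8 <- function(samples_per_pixel, bits, what) {
  if (!identical(as.integer(samples_per_pixel), 3L) ||
      any(as.integer(bits) != 8L)) {
    stop_wsi(sprintf("%s: only 8-bit 3-channel bright-field images are supported",
                     what), "unsupported_modality")
  }
}

# Generic region assembly from a tile-decoding callback: iterates the tiles
# overlapping `reg` on a (tw, th) grid and copies intersections.
assemble_region_from_tiles <- function(reg, tw, th, n_cols,
                                       decode_tile_fn) {
  out <- array(0L, dim = c(region_height(reg), region_width(reg), 3L))
  tx0 <- reg$x0 %/% tw; tx1 <- (reg$x1 - 1L) %/% tw
  ty0 <- reg$y0 %/% th; ty1 <- (reg$y1 - 1L) %/% th
  for (ty in ty0:ty1) {
    for (tx in tx0:tx1) {
      block <- decode_tile_fn(ty * n_cols + tx + 1L, tx, ty)
      bx0 <- tx * tw; by0 <- ty * th
      ix0 <- max(reg$x0, bx0); ix1 <- min(reg$x1, bx0 + tw)
      iy0 <- max(reg$y0, by0); iy1 <- min(reg$y1, by0 + th)
      out[(iy0 - reg$y0 + 1L):(iy1 - reg$y0),
          (ix0 - reg$x0 + 1L):(ix1 - reg$x0), ] <-
        block[(iy0 - by0 + 1L):(iy1 - by0),
              (ix0 - bx0 + 1L):(ix1 - bx0), , drop = FALSE]
    }
  }
  out
}

# --- TIFF / SVS -------------------------------------------------------------

open_source_tiff <- function(path) {
  parsed <- tiff_parse(path)
  ifd0 <- parsed$ifds[[1]]
  if (!tiff_is_tiled(ifd0)) {
    stop_wsi(sprintf("'%s': untiled TIFF not supported (strip-based layout)",
                     path), "untiled_tiff")
  }
  tiled <- Filter(tiff_is_tiled, parsed$ifds)
  # associated images (e.g. the SVS thumbnail IFD) are untiled and excluded
  desc <- tiff_tag(ifd0, 270) %||% ""
  is_svs <- startsWith(desc, "Aperio")

  check_rgb8(tiff_tag(ifd0, 277) %||% 1, tiff_tag(ifd0, 258) %||% 8, path)
  codec <- tiff_compression_to_codec(tiff_tag(ifd0, 259) %||% 1)
  if (is.null(codec)) {
    stop_wsi(sprintf("'%s': unsupported TIFF compression %s", path,
                     tiff_tag(ifd0, 259)), "unsupported_modality")
  }
  pred <- tiff_tag(ifd0, 317) %||% 1
  if (pred != 1) {
    stop_wsi(sprintf("'%s': TIFF predictor %s not supported", path, pred),
             "unsupported_modality")
  }

  w0 <- tiff_tag(ifd0, 256)
  levels <- lapply(tiled, function(ifd) {
    g <- image_geometry(tiff_tag(ifd, 256), tiff_tag(ifd, 257),
                        tiff_tag(ifd, 322), tiff_tag(ifd, 323))
    list(downsample = round(w0 / g$width), geometry = g)
  })
  ds <- vapply(levels, function(l) l$downsample, numeric(1))
  levels <- levels[order(ds)]
  if (any(diff(vapply(levels, function(l) l$downsample, numeric(1))) <= 0)) {
    stop_wsi(sprintf("'%s': level downsamples are not strictly increasing", path),
             "unsupported_format")
  }

  if (is_svs) {
    resolution <- parse_svs_description(desc)
  } else {
    unit_code <- tiff_tag(ifd0, 296) %||% 2
    unit <- switch(as.character(unit_code), `2` = "inch", `3` = "centimeter",
                   "none")
    xr <- tiff_tag(ifd0, 282)
    yr <- tiff_tag(ifd0, 283)
    resolution <- resolution_info(
      mpp_x = if (is.null(xr)) NA_real_ else mpp_from_tiff(xr[1], unit),
      mpp_y = if (is.null(yr)) NA_real_ else mpp_from_tiff(yr[1], unit))
  }

  src <- list(
    format = if (is_svs) "svs" else "tiff",
    path = path,
    parsed = parsed,
    tiled_ifds = tiled[order(ds)],
    geometry = levels[[1]]$geometry,
    resolution = resolution,
    levels = levels,
    codec = codec,
    can_yield_encoded_tiles = codec %in% c("jpeg", "jpeg2000")
  )
  structure(src, class = c("wsi_source_tiff", "wsi_source"))
}

tiff_decode_tile_index <- function(src, level, tile_index) {
  ifd <- src$tiled_ifds[[level]]
  bytes <- tiff_read_tile_bytes(src$path, ifd, tile_index)
  if (src$codec == "jpeg") {
    bytes <- jpeg_merge_tables(tiff_tag(ifd, 347), bytes)
  }
  g <- src$levels[[level]]$geometry
  decode_tile(bytes, src$codec, width = g$tile_width, height = g$tile_height)
}

#' @export
read_region.wsi_source_tiff <- function(src, reg, level = 1L, ...) {
  check_region_bounds(src, reg, level)
  g <- src$levels[[level]]$geometry
  n_cols <- ceil_div(g$width, g$tile_width)
  assemble_region_from_tiles(reg, g$tile_width, g$tile_height, n_cols,
                             function(i, tx, ty) tiff_decode_tile_index(src, level, i))
}

#' @export
iter_encoded_tiles.wsi_source_tiff <- function(src, level = 1L) {
  if (!src$can_yield_encoded_tiles) {
    stop_wsi(sprintf("TIFF with codec '%s' cannot yield encoded tiles; only jpeg and jpeg2000 streams can be repackaged",
                     src$codec), "transcode_unsupported")
  }
  ifd <- src$tiled_ifds[[level]]
  tables <- tiff_tag(ifd, 347)
  n <- length(tiff_tag(ifd, 324))
  i <- 0L
  list(n = n, next_tile = function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    bytes <- tiff_read_tile_bytes(src$path, ifd, i)
    if (src$codec == "jpeg") bytes <- jpeg_merge_tables(tables, bytes)
    encoded_tile(i, src$codec, bytes)
  })
}

# --- NGFF -------------------------------------------------------------------

open_source_ngff <- function(path) {
  parsed <- ngff_parse(path)
  lv0 <- parsed$levels[[1]]
  levels <- lapply(parsed$levels, function(lv) {
    list(downsample = round(lv0$dims$w / lv$dims$w),
         geometry = image_geometry(lv$dims$w, lv$dims$h, lv$dims$cw, lv$dims$ch))
  })
  codec <- switch(parsed$levels[[1]]$compressor %||% "raw",
                  raw = "raw", zlib = "deflate", gzip = "deflate",
                  jpeg = "jpeg",
                  stop_wsi(sprintf("unsupported NGFF compressor '%s'",
                                   parsed$levels[[1]]$compressor),
                           "unsupported_modality"))
  src <- list(
    format = "ngff",
    path = path,
    parsed = parsed,
    geometry = levels[[1]]$geometry,
    resolution = ngff_resolution(parsed),
    levels = levels,
    codec = codec,
    can_yield_encoded_tiles = codec == "jpeg"
  )
  structure(src, class = c("wsi_source_ngff", "wsi_source"))
}

#' @export
read_region.wsi_source_ngff <- function(src, reg, level = 1L, ...) {
  check_region_bounds(src, reg, level)
  g <- src$levels[[level]]$geometry
  assemble_region_from_tiles(reg, g$tile_width, g$tile_height, NA,
                             function(i, tx, ty) ngff_read_chunk(src$parsed, level, ty, tx))
}

#' @export
iter_encoded_tiles.wsi_source_ngff <- function(src, level = 1L) {
  if (src$codec != "jpeg") {
    stop_wsi(sprintf("NGFF store with compressor '%s' cannot yield encoded tiles",
                     src$codec), "transcode_unsupported")
  }
  lv <- src$parsed$levels[[level]]
  g <- src$levels[[level]]$geometry
  gd <- tile_grid_dims(g)
  n <- gd[1] * gd[2]
  i <- 0L
  list(n = n, next_tile = function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    tx <- (i - 1L) %% gd[1]
    ty <- (i - 1L) %/% gd[1]
    key <- if (src$parsed$axes_order == "cyx") {
      ngff_chunk_key(src$path, lv$path, 0L, ty, tx, lv$sep)
    } else {
      ngff_chunk_key(src$path, lv$path, ty, tx, 0L, lv$sep)
    }
    encoded_tile(i, "jpeg", readBin(key, "raw", file.size(key)))
  })
}

# --- DICOM ------------------------------------------------------------------

open_source_dicom <- function(path) {
  parsed <- dicom_parse(path)
  org <- parsed[["0020,9311"]]
  if (!is.null(org) && !identical(org, "TILED_FULL")) {
    stop_wsi(sprintf("'%s': only TILED_FULL DICOM frame organisation is supported",
                     path), "unsupported_modality")
  }
  check_rgb8(parsed[["0028,0002"]] %||% 1, parsed[["0028,0100"]] %||% 8, path)
  photometric <- parsed[["0028,0004"]] %||% "RGB"
  if (!photometric %in% c("RGB", "YBR_FULL_422", "YBR_FULL")) {
    stop_wsi(sprintf("'%s': photometric interpretation %s not supported",
                     path, photometric), "unsupported_modality")
  }
  tw <- parsed[["0028,0011"]]
  th <- parsed[["0028,0010"]]
  width <- parsed[["0048,0006"]]
  height <- parsed[["0048,0007"]]
  if (is.null(width) || is.null(height)) {
    stop_wsi(sprintf("'%s': total pixel matrix size missing", path),
             "unsupported_format")
  }
  g <- image_geometry(width, height, tw, th)
  gd <- tile_grid_dims(g)
  n_frames <- as.integer(parsed[["0028,0008"]] %||% length(parsed$pixel_data$offsets))
  if (n_frames != gd[1] * gd[2] ||
      length(parsed$pixel_data$offsets) != n_frames) {
    stop_wsi(sprintf("'%s': frame count %d does not match the %d x %d TILED_FULL grid",
                     path, n_frames, gd[1], gd[2]), "unsupported_format")
  }
  spacing <- parsed[["0028,0030"]]
  resolution <- if (is.null(spacing)) resolution_info() else
    resolution_info(mpp_x = spacing[2] * 1000, mpp_y = spacing[1] * 1000)

  src <- list(
    format = "dicom",
    path = path,
    parsed = parsed,
    geometry = g,
    resolution = resolution,
    levels = list(list(downsample = 1, geometry = g)),
    codec = parsed$codec,
    photometric = photometric,
    can_yield_encoded_tiles = TRUE
  )
  structure(src, class = c("wsi_source_dicom", "wsi_source"))
}

#' @export
read_region.wsi_source_dicom <- function(src, reg, level = 1L, ...) {
  check_region_bounds(src, reg, level)
  g <- src$geometry
  n_cols <- ceil_div(g$width, g$tile_width)
  assemble_region_from_tiles(reg, g$tile_width, g$tile_height, n_cols,
    function(i, tx, ty) {
      decode_tile(dicom_read_frame_bytes(src$parsed, i), src$codec,
                  width = g$tile_width, height = g$tile_height)
    })
}

#' @export
iter_encoded_tiles.wsi_source_dicom <- function(src, level = 1L) {
  n <- length(src$parsed$pixel_data$offsets)
  i <- 0L
  list(n = n, next_tile = function() {
    if (i >= n) return(NULL)
    i <<- i + 1L
    encoded_tile(i, src$codec, dicom_read_frame_bytes(src$parsed, i))
  })
}
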