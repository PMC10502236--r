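# Deterministic synthetic slides with a closed-form pixel oracle.
#
# Every cross-module equality test in the package reduces to this function:
# because each pixel value is a pure function of its coordinates, any region
# of any generated slide can be verified without reference files. The pattern
# mixes smooth content (linear ramp, R), high-frequency content (XOR, G) and
# a 64-px checkerboard (B) so that off-by-one shifts, transposes and
# tile-order bugs cannot cancel out.

#' Closed-form oracle pixel value
#'
#' @param x,y 0-based pixel coordinates (vectors of equal length, recycled).
#' @return Integer matrix with columns R, G, B, one row per coordinate pair.
#' @examples
#' oracle_pixel(0, 0)    # 0 0 0
#' oracle_pixel(64, 0)   # 192 64 255
#' @export
oracle_pixel <- function(x, y) {
  x <- as.integer(x); y <- as.integer(y)
  if (any(x < 0) || any(y < 0)) {
    stop_wsi("oracle coordinates must be >= 0", "invalid_parameter")
  }
  cbind(R = (7L * x + 13L * y) %% 256L,
        G = bitwXor(x, y) %% 256L,
        B = 255L * (((x %/% 64L) + (y %/% 64L)) %% 2L))
}

#' Oracle pixel block for a region
#'
#' @param reg A [region()] (or anything with x0, y0, x1, y1).
#' @return Integer array `c(height, width, 3)` of oracle values.
#' @export
oracle_block <- function(reg) {
  xs <- reg$x0:(reg$x1 - 1L)
  ys <- reg$y0:(reg$y1 - 1L)
  h <- length(ys); w <- length(xs)
  X <- matrix(xs, nrow = h, ncol = w, byrow = TRUE)
  Y <- matrix(ys, nrow = h, ncol = w)
  out <- array(0L, dim = c(h, w, 3L))
  out[, , 1] <- (7L * X + 13L * Y) %% 256L
  out[, , 2] <- bitwXor(as.integer(X), as.integer(Y)) %% 256L
  out[, , 3] <- 255L * (((X %/% 64L) + (Y %/% 64L)) %% 2L)
  out
}

#' In-memory synthetic slide source
#'
#' A [SlideSource][open_source()] whose pixels are computed on demand from
#' the closed-form oracle (or a constant). Useful as a conversion input that
#' needs no file on disk.
#'
#' @param width,height Image extent in pixels.
#' @param tile_width,tile_height Nominal tile size reported by the source.
#' @param mpp Microns per pixel (scalar or length-2 `c(x, y)`), or `NULL`.
#' @param objective_power Optional nominal magnification.
#' @param pattern `"oracle"` or `"constant"`.
#' @param value Constant channel value when `pattern = "constant"`.
#' @return A slide source supporting [read_region()].
#' @export
synthetic_source <- function(width, height, tile_width = 512L,
                             tile_height = tile_width, mpp = NULL,
                             objective_power = NULL,
                             pattern = c("oracle", "constant"), value = 255L) {
  pattern <- match.arg(pattern)
  src <- list(
    format = "synthetic",
    path = NA_character_,
    geometry = image_geometry(width, height, tile_width, tile_height),
    resolution = resolution_info(mpp_x = if (is.null(mpp)) NA_real_ else mpp[[1]],
                                 mpp_y = if (is.null(mpp)) NA_real_ else
                                   mpp[[length(mpp)]],
                                 objective_power = objective_power),
    levels = NULL,  # filled below
    codec = "raw",
    can_yield_encoded_tiles = FALSE,
    pattern = pattern,
    value = as.integer(value)
  )
  src$levels <- list(list(downsample = 1, geometry = src$geometry))
  structure(src, class = c("wsi_source_synthetic", "wsi_source"))
}

#' @export
read_region.wsi_source_synthetic <- function(src, reg, level = 1L, ...) {
  check_region_bounds(src, reg, level)
  if (src$pattern == "oracle") {
    oracle_block(reg)
  } else {
    array(src$value, dim = c(region_height(reg), region_width(reg), 3L))
  }
}

#' Generate a synthetic slide file
#'
#' Writes an oracle-patterned (or constant) slide to disk in any supported
#' container format, using the ordinary writer path. With a lossless codec the
#' stored pixels equal [oracle_pixel()] everywhere.
#'
#' @param path Output path (directory for `"ngff"`).
#' @param format One of `"tiff"`, `"svs"`, `"ngff"`, `"dicom"`.
#' @param width,height,tile Pixel extent and tile size.
#' @param codec Tile codec: `"raw"`, `"deflate"`, `"jpeg"`, `"jpeg2000"`.
#' @param quality JPEG quality (ignored for lossless codecs).
#' @param mpp Microns per pixel (scalar or `c(x, y)`), or `NULL` for unknown.
#' @param objective_power Optional magnification carried into metadata.
#' @param pattern,value Pixel pattern, see [synthetic_source()].
#' @param seed Integer seed for deterministic container identifiers.
#' @return `path`, invisibly.
#' @export
generate_fixture <- function(path, format = c("tiff", "svs", "ngff", "dicom"),
                             width = 2048L, height = 1536L, tile = 256L,
                             codec = "deflate", quality = 85L, mpp = 0.25,
                             objective_power = NULL,
                             pattern = c("oracle", "constant"), value = 255L,
                             seed = 42L) {
  format <- match.arg(format)
  pattern <- match.arg(pattern)
  src <- synthetic_source(width, height, tile_width = tile, mpp = mpp,
                          objective_power = objective_power,
                          pattern = pattern, value = value)
  sink <- open_sink(path, format, image_geometry(width, height, tile),
                    resolution = src$resolution, codec = codec,
                    quality = quality, seed = seed)
  run_conversion(src, sink, workers = 1L, progress = FALSE)
  invisible(path)
}
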