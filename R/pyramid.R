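# Reduced-resolution pyramid levels and SVS thumbnails.
#
# Downsampling is a separable box (area-mean) filter: each output pixel is
# the arithmetic mean of its 2x2 source block (1x2/2x1/1x1 at odd edges,
# averaged over the pixels present), rounded half up — fixed so outputs are
# platform-deterministic. Source pyramid levels are never copied; every
# level is recomputed from level 0 (or iteratively from the previous level).

#' Pyramid specification
#'
#' @param factors Strictly increasing integer downsample factors relative to
#'   level 0; the first must be >= 2 and each must be a power-of-two multiple
#'   of the previous (levels are built by iterated halving).
#' @param thumbnail_max Longest-edge bound for SVS thumbnails (default 1024).
#' @return Object of class `wsi_pyramid_spec`.
#' @export
pyramid_spec <- function(factors, thumbnail_max = 1024L) {
  if (!length(factors) || any(factors != floor(factors))) {
    stop_wsi("pyramid factors must be integers", "invalid_parameter")
  }
  factors <- as.integer(factors)
  ratios <- factors / c(1L, factors[-length(factors)])
  if (factors[1] < 2 || any(diff(factors) <= 0) ||
      any(ratios != 2^round(log2(ratios)))) {
    stop_wsi(sprintf("pyramid factors must be strictly increasing, start >= 2, and chain by powers of two (got %s)",
                     paste(factors, collapse = ", ")), "invalid_parameter")
  }
  structure(list(factors = factors,
                 thumbnail_max = check_count(thumbnail_max, "thumbnail_max")),
            class = "wsi_pyramid_spec")
}

#' Halve an image by 2x2 box filtering
#'
#' @param pixels Integer array `c(h, w, 3)` (or a matrix for one channel).
#' @return Array of ceil-halved dimensions; each value the mean of its
#'   source block over the pixels present, rounded half up.
#' @examples
#' downsample_2x(matrix(c(1, 3, 2, 4), 2))  # 3 (mean 2.5 rounds up)
#' @export
downsample_2x <- function(pixels) {
  if (is.matrix(pixels)) {
    return(downsample_2x_mat(pixels))
  }
  d <- dim(pixels)
  out <- array(0L, dim = c(ceil_div(d[1], 2L), ceil_div(d[2], 2L), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- downsample_2x_mat(pixels[, , c])
  out
}

downsample_2x_mat <- function(M) {
  h <- nrow(M); w <- ncol(M)
  hh <- ceil_div(h, 2L); ww <- ceil_div(w, 2L)
  odd_r <- seq(1L, h, by = 2L)
  even_r <- seq.int(2L, length.out = h %/% 2L, by = 2L)
  S <- M[odd_r, , drop = FALSE]
  cr <- rep(1L, hh)
  if (length(even_r)) {
    S[seq_along(even_r), ] <- S[seq_along(even_r), , drop = FALSE] +
      M[even_r, , drop = FALSE]
    cr[seq_along(even_r)] <- 2L
  }
  odd_c <- seq(1L, w, by = 2L)
  even_c <- seq.int(2L, length.out = w %/% 2L, by = 2L)
  S2 <- S[, odd_c, drop = FALSE]
  cc <- rep(1L, ww)
  if (length(even_c)) {
    S2[, seq_along(even_c)] <- S2[, seq_along(even_c), drop = FALSE] +
      S[, even_c, drop = FALSE]
    cc[seq_along(even_c)] <- 2L
  }
  counts <- outer(cr, cc)
  matrix(as.integer(round_half_up(S2 / counts)), hh, ww)
}

# Area-mean resize to arbitrary (smaller) dimensions via interval-overlap
# weight matrices: out = A %*% M %*% B per channel.
area_mean_resize <- function(pixels, out_w, out_h) {
  d <- dim(pixels)
  A <- overlap_weights(d[1], out_h)
  B <- t(overlap_weights(d[2], out_w))
  out <- array(0L, dim = c(out_h, out_w, 3L))
  for (c in 1:3) {
    out[, , c] <- as.integer(round_half_up(A %*% pixels[, , c] %*% B))
  }
  out
}

# n_out x n_in matrix; row i holds the fractional coverage of input cells by
# output cell i, normalised to sum to 1.
overlap_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step
    b <- i * step
    j0 <- floor(a) + 1L
    j1 <- min(ceiling(b), n_in)
    for (j in j0:j1) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1))
    }
  }
  W / step
}

#' Generate a thumbnail from a slide source
#'
#' Aspect-preserving reduction of the full-resolution level to a longest
#' edge of at most `max_edge`: iterated 2x box halving while the halved
#' longest edge is still >= `max_edge`, then one area-mean resize for the
#' residual factor. Reads the source in row bands so no full-resolution copy
#' of the slide is ever held.
#'
#' @param source A slide source.
#' @param max_edge Longest-edge bound in pixels (>= 1).
#' @param level Source level to reduce (default 1).
#' @return Integer pixel array.
#' @export
make_thumbnail <- function(source, max_edge = 1024L, level = 1L) {
  max_edge <- check_count(max_edge, "max_edge")
  g <- source$levels[[level]]$geometry
  w <- g$width; h <- g$height
  if (max(w, h) <= max_edge) {
    return(read_region(source, region(0, 0, w, h), level = level))
  }
  # first halving streams over row bands; later halvings are in memory
  cur <- halve_streaming(source, level)
  while (max(ceil_div(dim(cur)[2], 2L), ceil_div(dim(cur)[1], 2L)) >= max_edge) {
    cur <- downsample_2x(cur)
  }
  if (w >= h) {
    tw <- min(max_edge, w)
    th <- max(1L, as.integer(round(h * tw / w)))
  } else {
    th <- min(max_edge, h)
    tw <- max(1L, as.integer(round(w * th / h)))
  }
  if (all(dim(cur)[1:2] == c(th, tw))) return(cur)
  area_mean_resize(cur, tw, th)
}

halve_streaming <- function(source, level, band_rows = 1024L) {
  g <- source$levels[[level]]$geometry
  w <- g$width; h <- g$height
  out <- array(0L, dim = c(ceil_div(h, 2L), ceil_div(w, 2L), 3L))
  y <- 0L
  while (y < h) {
    y1 <- min(y + band_rows, h)
    band <- read_region(source, region(0, y, w, y1), level = level)
    small <- downsample_2x(band)
    out[(y %/% 2L + 1L):(y %/% 2L + dim(small)[1]), , ] <- small
    y <- y1
  }
  out
}

#' Append reduced-resolution pyramid levels to a finalized output
#'
#' Builds each requested level from the previous stored level, tile by tile
#' (a read block of `ratio * tile` pixels per output tile), and appends it to
#' the container: reduced-image IFDs for TIFF/SVS, new datasets plus updated
#' multiscales metadata for NGFF. Level `k` has dimensions
#' `ceil(level0 / factor_k)`. Multi-resolution DICOM (separate objects per
#' level) is not supported.
#'
#' @param path A finalized single-level TIFF/SVS/NGFF output of this
#'   package.
#' @param spec A [pyramid_spec()] (or a bare factor vector).
#' @return Summary list: `path`, `levels` (dimensions per level, level 0
#'   first), invisibly.
#' @export
append_levels <- function(path, spec) {
  if (!inherits(spec, "wsi_pyramid_spec")) spec <- pyramid_spec(spec)
  src <- open_source(path)
  if (src$format == "dicom") {
    stop_wsi("pyramid levels cannot be appended to a DICOM output",
             "invalid_parameter")
  }
  if (length(src$levels) > 1L) {
    stop_wsi(sprintf("'%s' already has %d levels; pyramid can only be appended to a single-level output",
                     path, length(src$levels)), "invalid_parameter")
  }
  g0 <- src$geometry
  prev_factor <- 1L
  dims <- list(c(g0$width, g0$height))
  for (f in spec$factors) {
    ratio <- f %/% prev_factor
    append_one_level(path, f, ratio)
    prev_factor <- f
    dims <- c(dims, list(c(ceil_div(g0$width, f), ceil_div(g0$height, f))))
  }
  invisible(list(path = path, levels = dims))
}

# Build the next level from the deepest existing one and append it.
append_one_level <- function(path, factor, ratio) {
  src <- open_source(path)  # re-parse: includes levels appended so far
  prev_level <- length(src$levels)
  pg <- src$levels[[prev_level]]$geometry
  g0 <- src$geometry
  new_w <- ceil_div(g0$width, factor)
  new_h <- ceil_div(g0$height, factor)
  geom <- image_geometry(new_w, new_h, g0$tile_width, g0$tile_height)
  n_half <- as.integer(round(log2(ratio)))

  make_tile <- function(tx, ty) {
    # the source block behind one output tile, clipped to the level extent
    bx0 <- tx * geom$tile_width * ratio
    by0 <- ty * geom$tile_height * ratio
    bx1 <- min(bx0 + geom$tile_width * ratio, pg$width)
    by1 <- min(by0 + geom$tile_height * ratio, pg$height)
    block <- read_region(src, region(bx0, by0, bx1, by1), level = prev_level)
    for (k in seq_len(n_half)) block <- downsample_2x(block)
    out <- array(255L, dim = c(geom$tile_height, geom$tile_width, 3L))
    d <- dim(block)
    out[seq_len(d[1]), seq_len(d[2]), ] <- block
    out
  }

  gd <- tile_grid_dims(geom)
  if (src$format %in% c("tiff", "svs")) {
    w <- tiff_writer_open(path, append = TRUE)
    n <- gd[1] * gd[2]
    offsets <- numeric(n)
    bytecounts <- numeric(n)
    i <- 0L
    for (ty in 0:(gd[2] - 1L)) {
      for (tx in 0:(gd[1] - 1L)) {
        i <- i + 1L
        stream <- encode_tile(make_tile(tx, ty), src$codec, 85L)
        offsets[i] <- tiff_writer_put_block(w, stream)
        bytecounts[i] <- length(stream)
      }
    }
    tiff_writer_add_ifd(w, tiff_level_entries(geom, src$codec, NULL,
                                              offsets, bytecounts,
                                              reduced = TRUE,
                                              bigtiff = w$bigtiff))
    tiff_writer_close(w)
  } else {  # ngff
    ds_name <- as.character(prev_level)  # datasets "0", "1", ...
    dir.create(file.path(path, ds_name))
    quality <- 85L
    ngff_write_json(ngff_zarray(new_h, new_w, geom$tile_height,
                                geom$tile_width, src$codec, quality),
                    file.path(path, ds_name, ".zarray"))
    for (ty in 0:(gd[2] - 1L)) {
      for (tx in 0:(gd[1] - 1L)) {
        stream <- ngff_chunk_encode(make_tile(tx, ty), src$codec, quality)
        writeBin(stream, ngff_chunk_key(path, ds_name, 0L, ty, tx))
      }
    }
    parsed <- ngff_parse(path)
    downs <- c(vapply(seq_along(parsed$levels), function(i) {
      round(parsed$levels[[1]]$dims$w / parsed$levels[[i]]$dims$w)
    }, numeric(1)), factor)
    lv_list <- lapply(seq_along(downs), function(i) {
      list(path = as.character(i - 1L), downsample = downs[i])
    })
    ngff_write_json(ngff_multiscales_attrs(lv_list, ngff_resolution(parsed)),
                    file.path(path, ".zattrs"))
  }
  invisible(path)
}
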