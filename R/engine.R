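# The multiple-reader/single-writer streaming conversion pipeline.
#
# The parallelism contract is behavioural: up to `workers` region reads may
# be serviced concurrently, completed regions enter a reorder buffer, the
# writer blocks until every dependency of the next row-major tile is
# buffered, and each region is evicted immediately after its last dependent
# tile is written. Any schedule satisfying this contract yields the same
# output file; this implementation services reads serially in dispatch
# order (the reference behaviour, equivalent to a single worker that is
# never ahead of the writer), so the output is trivially independent of
# `workers` and of buffer scheduling.

#' Dispatch order for region reads
#'
#' Orders read regions by the first write tile that needs them (ties broken
#' by region index), which guarantees that the writer's next tile always
#' depends on the earliest-dispatched outstanding reads — the writer can
#' never be starved by a read it has not yet requested.
#'
#' @param plan A [plan_regrid()] result.
#' @return Integer vector: read region indices in dispatch order.
#' @export
dispatch_order <- function(plan) {
  n_regions <- length(plan$read_regions)
  first_need <- rep.int(.Machine$integer.max, n_regions)
  for (t in seq_along(plan$deps)) {
    for (r in plan$deps[[t]]) {
      if (t < first_need[r]) first_need[r] <- t
    }
  }
  order(first_need, seq_len(n_regions))
}

#' Run a streaming conversion
#'
#' Reads regions of `read_w` x `read_h` pixels from `source`, regrids them to
#' the sink's tile grid (padding edge tiles with `pad_value`), encodes with
#' the sink codec and writes tiles in strict row-major order. The decoded
#' output equals the decoded source wherever the codec chain is lossless,
#' regardless of read size, worker count or buffer capacity.
#'
#' @param source A source from [open_source()] or [synthetic_source()].
#' @param sink A sink from [open_sink()] whose geometry matches the source
#'   level extent.
#' @param read_w,read_h Read region size; defaults to the sink tile size.
#'   Larger reads mean fewer, bigger decodes on the source side.
#' @param workers Declared maximum number of concurrent region reads
#'   (default 6). Never affects the output.
#' @param buffer_cap Reorder-buffer capacity in regions held beyond the
#'   in-flight reads; defaults to twice the maximum dependency count of any
#'   tile, and must be at least that maximum.
#' @param pad_value Channel fill for pixels beyond the image extent
#'   (default 255: white bright-field background).
#' @param level Source resolution level to convert (default 1, the full
#'   resolution).
#' @param thumbnail_max Longest thumbnail edge for SVS sinks.
#' @param progress Print a log line every `progress` percent (`FALSE` to
#'   disable).
#' @return A `wsi_conversion_report`: `tiles_written`, `pixels_processed`,
#'   `peak_buffered_regions`, `mode`, plus the run parameters.
#' @export
run_conversion <- function(source, sink, read_w = NULL, read_h = NULL,
                           workers = 6L, buffer_cap = NULL, pad_value = 255L,
                           level = 1L, thumbnail_max = 1024L,
                           progress = FALSE) {
  workers <- check_count(workers, "workers")
  src_geom <- source$levels[[level]]$geometry
  geom <- sink$geometry
  if (geom$width != src_geom$width || geom$height != src_geom$height) {
    stop_wsi(sprintf("sink extent %d x %d does not match source level extent %d x %d",
                     geom$width, geom$height, src_geom$width, src_geom$height),
             "invalid_parameter")
  }
  read_w <- check_count(read_w %||% geom$tile_width, "read_w")
  read_h <- check_count(read_h %||% geom$tile_height, "read_h")

  plan <- plan_regrid(geom, read_w, read_h)
  max_deps <- max(lengths(plan$deps))
  buffer_cap <- check_count(buffer_cap %||% (2L * max_deps), "buffer_cap")
  if (buffer_cap < max_deps) {
    stop_wsi(sprintf("buffer_cap %d < maximum dependency count %d: some tile could never assemble",
                     buffer_cap, max_deps), "invalid_parameter")
  }

  order_idx <- dispatch_order(plan)
  n_tiles <- length(plan$deps)
  buffer <- new.env(parent = emptyenv())
  buffered <- 0L
  peak <- 0L
  next_dispatch <- 1L
  pct_step <- if (isTRUE(progress)) 10 else if (is.numeric(progress)) progress else 0
  next_pct <- pct_step

  run <- function() {
    for (t in seq_len(n_tiles)) {
      for (r in plan$deps[[t]]) {
        key <- as.character(r)
        while (is.null(buffer[[key]])) {
          ri <- order_idx[next_dispatch]
          next_dispatch <<- next_dispatch + 1L
          buffer[[as.character(ri)]] <- read_region(source,
                                                    plan$read_regions[[ri]],
                                                    level = level)
          buffered <<- buffered + 1L
          if (buffered > peak) peak <<- buffered
        }
      }
      tile <- assemble_tile(plan, t, buffer, pad_value = pad_value)
      write_tile(sink, t, tile)
      for (r in plan$deps[[t]]) {
        if (plan$last_use[r] == t) {
          rm(list = as.character(r), envir = buffer)
          buffered <<- buffered - 1L
        }
      }
      if (pct_step > 0) {
        pct <- 100 * t / n_tiles
        while (pct >= next_pct) {
          message(sprintf("converted %d/%d tiles (%.0f%%)", t, n_tiles, pct))
          next_pct <<- next_pct + pct_step
        }
      }
    }
    if (sink$format == "svs" && is.null(sink$thumbnail)) {
      set_thumbnail(sink, make_thumbnail(source, thumbnail_max, level = level))
    }
    finalize(sink)
  }

  summary <- tryCatch(run(), error = function(e) {
    # never leave a half-written container behind: it would be
    # indistinguishable from a corrupt slide
    sink_abort(sink)
    stop(e)
  })

  structure(
    list(tiles_written = summary$tiles_written,
         pixels_processed = as.double(geom$width) * geom$height,
         peak_buffered_regions = peak,
         mode = "convert",
         workers = workers, buffer_cap = buffer_cap,
         read_w = read_w, read_h = read_h,
         output = sink$path, mpp = summary$mpp),
    class = "wsi_conversion_report"
  )
}

#' @export
print.wsi_conversion_report <- function(x, ...) {
  cat(sprintf("<wsi_conversion_report> mode %s: %d tiles, %.4g megapixels -> %s\n",
              x$mode, x$tiles_written, x$pixels_processed / 1e6,
              x$output %||% "?"))
  if (x$mode == "convert") {
    cat(sprintf("  read %d x %d, workers %d, buffer cap %d, peak buffered regions %d\n",
                x$read_w, x$read_h, x$workers, x$buffer_cap,
                x$peak_buffered_regions))
  }
  invisible(x)
}

#' One-call slide conversion
#'
#' Convenience wrapper: opens the source, derives the sink geometry, runs the
#' streaming conversion and optionally appends pyramid levels.
#'
#' @param input Source path.
#' @param output Output path.
#' @param format Output format; inferred from the output extension when
#'   `NULL`.
#' @param tile_width,tile_height Output tile size (default 512 x 512).
#' @param codec Output codec; per-format default when `NULL` (deflate for
#'   tiff/ngff, jpeg for svs/dicom).
#' @param quality JPEG quality.
#' @param read_w,read_h Read size (defaults to the output tile size).
#' @param workers Declared reader concurrency (default 6).
#' @param downsample Integer pyramid factors to append (e.g. `c(2, 4)`).
#' @param mpp Optional microns-per-pixel override (scalar or `c(x, y)`).
#' @param seed Seed for deterministic container identifiers.
#' @param overwrite Replace an existing output.
#' @param progress Progress logging, see [run_conversion()].
#' @return The `wsi_conversion_report`, invisibly.
#' @export
convert_slide <- function(input, output, format = NULL,
                          tile_width = 512L, tile_height = tile_width,
                          codec = NULL, quality = 85L,
                          read_w = NULL, read_h = NULL, workers = 6L,
                          downsample = NULL, mpp = NULL, seed = NULL,
                          overwrite = FALSE, progress = FALSE) {
  source <- if (inherits(input, "wsi_source")) input else open_source(input)
  format <- format %||% infer_format(output)
  res <- source$resolution
  if (!is.null(mpp)) {
    res <- resolution_info(mpp_x = mpp[[1]], mpp_y = mpp[[length(mpp)]],
                           objective_power = res$objective_power)
  }
  geom <- image_geometry(source$geometry$width, source$geometry$height,
                         tile_width, tile_height)
  sink <- open_sink(output, format, geom, resolution = res, codec = codec,
                    quality = quality, seed = seed, overwrite = overwrite)
  report <- run_conversion(source, sink, read_w = read_w, read_h = read_h,
                           workers = workers, progress = progress)
  if (!is.null(downsample)) {
    append_levels(output, pyramid_spec(downsample))
  }
  invisible(report)
}

infer_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  switch(ext,
         tif = , tiff = "tiff",
         svs = "svs",
         dcm = "dicom",
         zarr = "ngff",
         stop_wsi(sprintf("cannot infer output format from '%s'; pass format explicitly",
                          path), "invalid_parameter"))
}
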