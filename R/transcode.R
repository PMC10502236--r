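# Container-to-container repackaging of encoded tiles without decode or
# re-encode. The stored tile streams of the source are copied byte-for-byte
# into the target layout; tile size and codec are carried over unchanged
# (retiling is impossible without decoding). The pixel-decode counter
# (decode_count()) stays at zero on this path.

#' Can a source be transcoded into a target format?
#'
#' Transcoding requires that the source can yield self-contained encoded
#' tile streams (JPEG or JPEG 2000) and that the target container stores
#' that codec as-is: tiff/svs and dicom accept both stream codecs; ngff
#' accepts jpeg only.
#'
#' @param source A source from [open_source()].
#' @param target_format One of `"tiff"`, `"svs"`, `"ngff"`, `"dicom"`.
#' @return List with `ok` (logical) and `reason` (text; why not, or what
#'   will be copied).
#' @export
can_transcode <- function(source, target_format = c("tiff", "svs", "ngff", "dicom")) {
  target_format <- match.arg(target_format)
  if (!isTRUE(source$can_yield_encoded_tiles)) {
    return(list(ok = FALSE,
                reason = sprintf("source codec '%s' is not stored as copyable encoded tile streams",
                                 source$codec)))
  }
  if (!source$codec %in% c("jpeg", "jpeg2000")) {
    return(list(ok = FALSE,
                reason = sprintf("codec '%s' cannot be repackaged without re-encoding",
                                 source$codec)))
  }
  allowed <- CODECS_BY_FORMAT[[target_format]]
  if (!source$codec %in% allowed ||
      (target_format == "ngff" && source$codec != "jpeg")) {
    return(list(ok = FALSE,
                reason = sprintf("target format '%s' does not store '%s' streams (accepts: %s)",
                                 target_format, source$codec,
                                 paste(intersect(allowed, c("jpeg", "jpeg2000")),
                                       collapse = ", "))))
  }
  list(ok = TRUE,
       reason = sprintf("%d %s tiles of %d x %d px copied without re-encoding",
                        prod(tile_grid_dims(source$geometry)), source$codec,
                        source$geometry$tile_width, source$geometry$tile_height))
}

#' Repackage encoded tiles into a new container
#'
#' Copies every stored tile stream of `source` into `sink` without decoding.
#' Each stream's entropy-coded segment in the output is byte-identical to the
#' input's, so the decoded output equals the decoded source exactly.
#' Resolution metadata is translated through the metadata layer like any
#' conversion.
#'
#' @param source A source for which [can_transcode()] is true.
#' @param sink A sink opened with the source's geometry, tile size and
#'   codec.
#' @param thumbnail_max Longest thumbnail edge for SVS sinks (the thumbnail
#'   is regenerated from the source pixels — the only decodes on an SVS
#'   transcode).
#' @return A `wsi_conversion_report` with `mode = "transcode"`.
#' @export
run_transcode <- function(source, sink, thumbnail_max = 1024L) {
  decision <- can_transcode(source, sink$format)
  if (!decision$ok) {
    stop_wsi(decision$reason, "transcode_unsupported")
  }
  if (sink$codec != source$codec) {
    stop_wsi(sprintf("sink codec '%s' must equal source codec '%s' for transcode",
                     sink$codec, source$codec), "transcode_unsupported")
  }
  g <- sink$geometry
  sg <- source$geometry
  if (g$width != sg$width || g$height != sg$height ||
      g$tile_width != sg$tile_width || g$tile_height != sg$tile_height) {
    stop_wsi("transcode requires identical geometry and tile size on both sides",
             "invalid_parameter")
  }

  run <- function() {
    it <- iter_encoded_tiles(source)
    for (i in seq_len(it$n)) {
      tile <- it$next_tile()
      write_encoded_tile(sink, i, tile)
    }
    if (sink$format == "svs" && is.null(sink$thumbnail)) {
      set_thumbnail(sink, make_thumbnail(source, thumbnail_max))
    }
    finalize(sink)
  }
  summary <- tryCatch(run(), error = function(e) {
    sink_abort(sink)
    stop(e)
  })

  structure(
    list(tiles_written = summary$tiles_written,
         pixels_processed = as.double(g$width) * g$height,
         peak_buffered_regions = 0L,
         mode = "transcode",
         output = sink$path, mpp = summary$mpp),
    class = "wsi_conversion_report"
  )
}

#' One-call transcode
#'
#' @param input Source path (must hold JPEG or JPEG 2000 tiles).
#' @param output Output path.
#' @param format Output format; inferred from the extension when `NULL`.
#' @param seed Seed for deterministic container identifiers.
#' @param overwrite Replace an existing output.
#' @return The `wsi_conversion_report`, invisibly.
#' @export
transcode_slide <- function(input, output, format = NULL, seed = NULL,
                            overwrite = FALSE) {
  source <- if (inherits(input, "wsi_source")) input else open_source(input)
  format <- format %||% infer_format(output)
  decision <- can_transcode(source, format)
  if (!decision$ok) stop_wsi(decision$reason, "transcode_unsupported")
  sink <- open_sink(output, format, source$geometry,
                    resolution = source$resolution, codec = source$codec,
                    seed = seed, overwrite = overwrite)
  invisible(run_transcode(source, sink))
}
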