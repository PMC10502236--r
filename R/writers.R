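# Format adapters exposing a uniform streaming tile-write contract. Tiles
# must be written exactly once each, in row-major order, at full tile size
# (the engine pre-pads edge tiles); finalize() completes the container and
# checks nothing is missing. Output is deterministic: no timestamps are
# embedded and DICOM identifiers derive from an explicit seed.

CODECS_BY_FORMAT <- list(
  tiff = c("raw", "deflate", "jpeg", "jpeg2000"),
  svs = c("raw", "deflate", "jpeg", "jpeg2000"),
  ngff = c("raw", "deflate", "jpeg"),
  dicom = c("jpeg", "jpeg2000")
)

#' Open a slide sink for streaming tile writes
#'
#' Creates the container skeleton and embeds resolution metadata. Tiles are
#' then supplied by [write_tile()] (pixels, encoded with the sink codec) or
#' [write_encoded_tile()] (pre-encoded streams, stored without re-encoding),
#' and the container is completed by [finalize()].
#'
#' @param path Output file (directory for `"ngff"`). Must not already exist
#'   unless `overwrite = TRUE`.
#' @param format One of `"tiff"`, `"svs"`, `"ngff"`, `"dicom"`.
#' @param geometry Output [image_geometry()] (level 0 extent + tile size).
#' @param resolution A [resolution_info()]; unknown resolution is written as
#'   unknown, never defaulted.
#' @param codec Tile codec; supported pairs: tiff/svs take all of raw,
#'   deflate, jpeg, jpeg2000; ngff takes raw, deflate, jpeg; dicom takes jpeg
#'   and jpeg2000 (JPEG 2000 is encoded reversibly, i.e. lossless).
#' @param quality JPEG quality (1..100).
#' @param seed Integer seed making container identifiers (DICOM UIDs)
#'   deterministic; `NULL` for random.
#' @param overwrite Replace an existing output.
#' @return An object of class `wsi_sink` (a stateful handle).
#' @export
open_sink <- function(path, format = c("tiff", "svs", "ngff", "dicom"),
                      geometry, resolution = resolution_info(),
                      codec = NULL, quality = 85L, seed = NULL,
                      overwrite = FALSE) {
  format <- match.arg(format)
  codec <- codec %||% switch(format, dicom = "jpeg", svs = "jpeg", "deflate")
  check_codec(codec)
  if (!codec %in% CODECS_BY_FORMAT[[format]]) {
    stop_wsi(sprintf("format '%s' does not support codec '%s' (allowed: %s)",
                     format, codec,
                     paste(CODECS_BY_FORMAT[[format]], collapse = ", ")),
             "invalid_parameter")
  }
  if (!inherits(geometry, "wsi_geometry")) {
    stop_wsi("geometry must be an image_geometry()", "invalid_parameter")
  }
  if (file.exists(path) || dir.exists(path)) {
    if (!overwrite) {
      stop_wsi(sprintf("output '%s' already exists (use overwrite)", path),
               "invalid_parameter")
    }
    unlink(path, recursive = TRUE)
  }

  gd <- tile_grid_dims(geometry)
  s <- new.env(parent = emptyenv())
  s$format <- format
  s$path <- path
  s$geometry <- geometry
  s$resolution <- resolution
  s$codec <- codec
  s$quality <- as.integer(quality)
  s$seed <- seed
  s$n_tiles <- gd[1] * gd[2]
  s$next_index <- 1L
  s$bytes_written <- 0
  s$finalized <- FALSE
  s$accepts_encoded <- codec %in% c("jpeg", "jpeg2000")
  s$thumbnail <- NULL

  cls <- switch(format,
                tiff = "wsi_sink_tiff", svs = "wsi_sink_tiff",
                ngff = "wsi_sink_ngff", dicom = "wsi_sink_dicom")
  class(s) <- c(cls, "wsi_sink")
  sink_open(s)
  s
}

# Abort a sink: release its connection (if any) and remove partial output.
sink_abort <- function(s) {
  w <- s$writer
  if (!is.null(w) && !is.null(w$con) && !isTRUE(w$closed)) {
    w$closed <- TRUE
    tryCatch(close(w$con), error = function(e) NULL)
  }
  unlink(s$path, recursive = TRUE, force = TRUE)
  invisible(s)
}

sink_open <- function(s) UseMethod("sink_open")
sink_put_stream <- function(s, stream) UseMethod("sink_put_stream")
sink_finalize <- function(s) UseMethod("sink_finalize")

#' @export
print.wsi_sink <- function(x, ...) {
  cat(sprintf("<wsi_sink:%s> %s, codec %s, %d/%d tiles written\n",
              x$format, x$path, x$codec, x$next_index - 1L, x$n_tiles))
  invisible(x)
}

check_tile_sequence <- function(s, tile_index) {
  if (s$finalized) {
    stop_wsi("sink is already finalized", "sequencing_error")
  }
  if (tile_index != s$next_index) {
    stop_wsi(sprintf("tiles must be written in row-major order: expected tile %d, got %d",
                     s$next_index, tile_index), "sequencing_error")
  }
}

#' Write one tile of pixels
#'
#' Encodes `pixels` with the sink codec and appends it. Tiles must arrive in
#' row-major order and at full tile size; the assembler pads edge tiles.
#'
#' @param s A sink from [open_sink()].
#' @param tile_index 1-based row-major index; must be the next expected one.
#' @param pixels Integer array `c(tile_height, tile_width, 3)`.
#' @return The sink, invisibly.
#' @export
write_tile <- function(s, tile_index, pixels) {
  check_tile_sequence(s, tile_index)
  d <- dim(pixels)
  g <- s$geometry
  if (length(d) != 3L || d[1] != g$tile_height || d[2] != g$tile_width ||
      d[3] != 3L) {
    stop_wsi(sprintf("tile %d has shape (%s), expected (%d, %d, 3)",
                     tile_index, paste(d, collapse = ", "),
                     g$tile_height, g$tile_width), "shape_error")
  }
  stream <- sink_encode(s, pixels)
  sink_put_stream(s, stream)
  s$next_index <- s$next_index + 1L
  invisible(s)
}

# Sink-specific pixel serialisation: TIFF and DICOM store interleaved RGB
# tile streams; NGFF chunks are planar (c, y, x) C-order.
sink_encode <- function(s, pixels) UseMethod("sink_encode")

#' @export
sink_encode.default <- function(s, pixels) encode_tile(pixels, s$codec, s$quality)

#' @export
sink_encode.wsi_sink_ngff <- function(s, pixels) {
  ngff_chunk_encode(pixels, s$codec, s$quality)
}

#' Store a pre-encoded tile without re-encoding
#'
#' The transcode path: the self-contained stream is stored byte-for-byte; its
#' entropy-coded segment is never touched. The tile codec must match the sink
#' codec.
#'
#' @param s A sink from [open_sink()] with an encoded-stream codec.
#' @param tile_index 1-based row-major index; must be the next expected one.
#' @param tile An [encoded_tile()].
#' @return The sink, invisibly.
#' @export
write_encoded_tile <- function(s, tile_index, tile) {
  if (!s$accepts_encoded) {
    stop_wsi(sprintf("sink codec '%s' does not accept encoded tile streams",
                     s$codec), "transcode_unsupported")
  }
  if (!inherits(tile, "wsi_encoded_tile") || tile$codec != s$codec) {
    stop_wsi(sprintf("encoded tile codec '%s' does not match sink codec '%s'",
                     if (inherits(tile, "wsi_encoded_tile")) tile$codec else "?",
                     s$codec), "transcode_unsupported")
  }
  check_tile_sequence(s, tile_index)
  check_stream_signature(tile$stream, tile$codec, tile_index)
  sink_put_stream(s, tile$stream)
  s$next_index <- s$next_index + 1L
  invisible(s)
}

#' Attach the SVS thumbnail
#'
#' SVS outputs require a thumbnail image (stored as the second, untiled IFD)
#' before [finalize()] succeeds.
#'
#' @param s An SVS sink.
#' @param pixels Integer array `c(h, w, 3)`.
#' @return The sink, invisibly.
#' @export
set_thumbnail <- function(s, pixels) {
  if (s$format != "svs") {
    stop_wsi("thumbnails only apply to SVS outputs", "invalid_parameter")
  }
  s$thumbnail <- pixels
  invisible(s)
}

#' Finalize a slide sink
#'
#' Completes the container (IFD chain, zarr attributes, DICOM sequence
#' delimiter) after all grid tiles have been written, so that [open_source()]
#' can re-open the output.
#'
#' @param s A sink from [open_sink()].
#' @return A summary list: `tiles_written`, `bytes_written`, `mpp`.
#' @export
finalize <- function(s) {
  if (s$finalized) stop_wsi("sink is already finalized", "sequencing_error")
  written <- s$next_index - 1L
  if (written < s$n_tiles) {
    stop_wsi(sprintf("incomplete output: missing tiles %s",
                     paste(seq(written + 1L, s$n_tiles), collapse = ", ")),
             "incomplete_output")
  }
  if (s$format == "svs" && is.null(s$thumbnail)) {
    stop_wsi("SVS output requires a thumbnail before finalize", "incomplete_output")
  }
  sink_finalize(s)
  s$finalized <- TRUE
  list(tiles_written = written, bytes_written = s$bytes_written,
       mpp = c(s$resolution$mpp_x, s$resolution$mpp_y))
}

# --- TIFF / SVS sink --------------------------------------------------------

#' @export
sink_open.wsi_sink_tiff <- function(s) {
  projected <- as.double(s$geometry$width) * s$geometry$height * 3
  s$bigtiff <- projected > 2^32
  s$writer <- tiff_writer_open(s$path, bigtiff = s$bigtiff)
  s$offsets <- numeric(s$n_tiles)
  s$bytecounts <- numeric(s$n_tiles)
  invisible(s)
}

#' @export
sink_put_stream.wsi_sink_tiff <- function(s, stream) {
  off <- tiff_writer_put_block(s$writer, stream)
  s$offsets[s$next_index] <- off
  s$bytecounts[s$next_index] <- length(stream)
  s$bytes_written <- s$bytes_written + length(stream)
  invisible(s)
}

#' @export
sink_finalize.wsi_sink_tiff <- function(s) {
  description <- if (s$format == "svs") {
    emit_svs_description(s$resolution)
  } else {
    NULL
  }
  entries <- tiff_level_entries(s$geometry, s$codec, s$resolution,
                                s$offsets, s$bytecounts,
                                description = description,
                                reduced = FALSE, bigtiff = s$bigtiff)
  tiff_writer_add_ifd(s$writer, entries)
  if (s$format == "svs") {
    th <- s$thumbnail
    d <- dim(th)
    tcodec <- if (s$codec %in% c("jpeg", "jpeg2000")) "jpeg" else s$codec
    stream <- if (tcodec == "jpeg") {
      .cx_jpeg_encode(pixels_to_raw_interleaved(th), d[2], d[1], s$quality)
    } else if (tcodec == "deflate") {
      memCompress(pixels_to_raw_interleaved(th), type = "gzip")
    } else {
      pixels_to_raw_interleaved(th)
    }
    off <- tiff_writer_put_block(s$writer, stream)
    tiff_writer_add_ifd(s$writer,
                        tiff_strip_entries(d[2], d[1], tcodec, off,
                                           length(stream)))
  }
  tiff_writer_close(s$writer)
  invisible(s)
}

# --- NGFF sink --------------------------------------------------------------

#' @export
sink_open.wsi_sink_ngff <- function(s) {
  dir.create(s$path, recursive = TRUE)
  dir.create(file.path(s$path, "0"))
  ngff_write_json(list(zarr_format = 2L), file.path(s$path, ".zgroup"))
  g <- s$geometry
  ngff_write_json(ngff_zarray(g$height, g$width, g$tile_height, g$tile_width,
                              s$codec, s$quality),
                  file.path(s$path, "0", ".zarray"))
  s$grid <- tile_grid_dims(g)
  invisible(s)
}

#' @export
sink_put_stream.wsi_sink_ngff <- function(s, stream) {
  i <- s$next_index
  tx <- (i - 1L) %% s$grid[1]
  ty <- (i - 1L) %/% s$grid[1]
  key <- ngff_chunk_key(s$path, "0", 0L, ty, tx)
  writeBin(stream, key)
  s$bytes_written <- s$bytes_written + length(stream)
  invisible(s)
}

#' @export
sink_finalize.wsi_sink_ngff <- function(s) {
  attrs <- ngff_multiscales_attrs(list(list(path = "0", downsample = 1)),
                                  s$resolution)
  ngff_write_json(attrs, file.path(s$path, ".zattrs"))
  invisible(s)
}

# --- DICOM sink -------------------------------------------------------------

#' @export
sink_open.wsi_sink_dicom <- function(s) {
  s$writer <- dicom_writer_open(s$path, s$geometry, s$resolution, s$codec,
                                seed = s$seed)
  invisible(s)
}

#' @export
sink_put_stream.wsi_sink_dicom <- function(s, stream) {
  dicom_writer_put_frame(s$writer, stream)
  s$bytes_written <- s$bytes_written + length(stream)
  invisible(s)
}

#' @export
sink_finalize.wsi_sink_dicom <- function(s) {
  dicom_writer_close(s$writer)
  invisible(s)
}
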