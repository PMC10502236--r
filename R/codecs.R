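# Tile codec surface. A pixel block (integer array c(h, w, 3)) is serialised
# to interleaved RGB bytes, row-major, then entropy-coded. "raw" and "deflate"
# are lossless byte codecs; "jpeg" is baseline JFIF via libjpeg; "jpeg2000" is
# a reversible (5/3 wavelet, lossless) raw J2K codestream via openjpeg.

WSI_CODECS <- c("raw", "deflate", "jpeg", "jpeg2000")

check_codec <- function(codec) {
  if (!is.character(codec) || length(codec) != 1L || !codec %in% WSI_CODECS) {
    stop_wsi(sprintf("codec must be one of: %s", paste(WSI_CODECS, collapse = ", ")),
             "invalid_parameter")
  }
  codec
}

# environment-level instrumentation: tests and the transcode contract assert
# that no pixel decode happens on the transcode path.
.wsi_state <- new.env(parent = emptyenv())
.wsi_state$decode_count <- 0L

#' Pixel-decode instrumentation
#'
#' The transcode mode guarantees that no tile is ever decoded to pixels; the
#' package counts every entropy decode so tests can assert this.
#'
#' @return `decode_count()` returns the number of tile decodes since the last
#'   reset; `reset_decode_count()` zeroes it and returns the previous value.
#' @export
decode_count <- function() .wsi_state$decode_count

#' @rdname decode_count
#' @export
reset_decode_count <- function() {
  old <- .wsi_state$decode_count
  .wsi_state$decode_count <- 0L
  invisible(old)
}

# array c(h, w, 3) -> interleaved RGB bytes (R,G,B per pixel, row-major)
pixels_to_raw_interleaved <- function(arr) {
  as.raw(aperm(arr, c(3L, 2L, 1L)))
}

# inverse: bytes -> integer array c(h, w, 3)
raw_interleaved_to_pixels <- function(bytes, width, height) {
  a <- array(as.integer(bytes), dim = c(3L, width, height))
  aperm(a, c(3L, 2L, 1L))
}

#' Encode a pixel block with a tile codec
#'
#' @param pixels Integer array `c(h, w, 3)`, values 0..255.
#' @param codec One of `"raw"`, `"deflate"`, `"jpeg"`, `"jpeg2000"`.
#' @param quality JPEG quality 1..100 (ignored by the lossless codecs;
#'   JPEG 2000 is always encoded reversibly here).
#' @return Raw vector: the encoded, self-contained stream.
#' @export
encode_tile <- function(pixels, codec, quality = 85L) {
  check_codec(codec)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop_wsi("pixels must be an array of dim c(h, w, 3)", "shape_error")
  }
  bytes <- pixels_to_raw_interleaved(pixels)
  switch(codec,
    raw = bytes,
    deflate = memCompress(bytes, type = "gzip"),
    jpeg = .cx_jpeg_encode(bytes, d[2], d[1], as.integer(quality)),
    jpeg2000 = .cx_j2k_encode(bytes, d[2], d[1])
  )
}

#' Decode a tile stream to a pixel block
#'
#' @param stream Raw vector as produced by [encode_tile()] (or read from a
#'   container).
#' @param codec Codec the stream is encoded with.
#' @param width,height Tile dimensions; required for `"raw"` and `"deflate"`
#'   (the byte codecs carry no geometry), checked against the stream for the
#'   image codecs.
#' @return Integer array `c(height, width, 3)`.
#' @export
decode_tile <- function(stream, codec, width = NULL, height = NULL) {
  check_codec(codec)
  .wsi_state$decode_count <- .wsi_state$decode_count + 1L
  if (codec %in% c("raw", "deflate")) {
    if (is.null(width) || is.null(height)) {
      stop_wsi("width/height required to decode a byte-codec tile",
               "invalid_parameter")
    }
    bytes <- if (codec == "raw") stream else memDecompress(stream, type = "gzip")
    if (length(bytes) != 3L * width * height) {
      stop_wsi(sprintf("tile stream decodes to %d bytes, expected %d",
                       length(bytes), 3L * width * height), "corrupt_tile")
    }
    return(raw_interleaved_to_pixels(bytes, width, height))
  }
  dec <- if (codec == "jpeg") .cx_jpeg_decode(stream) else .cx_j2k_decode(stream)
  if (!is.null(width) && (dec$width != width || dec$height != height)) {
    stop_wsi(sprintf("decoded tile is %d x %d, expected %d x %d",
                     dec$width, dec$height, width, height), "corrupt_tile")
  }
  raw_interleaved_to_pixels(dec$data, dec$width, dec$height)
}

codec_is_lossless <- function(codec) codec %in% c("raw", "deflate", "jpeg2000")

# --- stream signature checks (used by the transcode safety net) -------------

jpeg_signature_ok <- function(stream) {
  n <- length(stream)
  n >= 4L &&
    stream[1] == as.raw(0xFF) && stream[2] == as.raw(0xD8) &&
    stream[n - 1L] == as.raw(0xFF) && stream[n] == as.raw(0xD9)
}

j2k_signature_ok <- function(stream) {
  n <- length(stream)
  if (n < 4L) return(FALSE)
  soc <- stream[1] == as.raw(0xFF) && stream[2] == as.raw(0x4F) &&
    stream[3] == as.raw(0xFF) && stream[4] == as.raw(0x51)
  jp2 <- n >= 12L && all(stream[1:8] == as.raw(c(0x00, 0x00, 0x00, 0x0C,
                                                 0x6A, 0x50, 0x20, 0x20)))
  soc || jp2
}

check_stream_signature <- function(stream, codec, index = NA_integer_) {
  ok <- switch(codec,
               jpeg = jpeg_signature_ok(stream),
               jpeg2000 = j2k_signature_ok(stream),
               TRUE)
  if (!ok) {
    stop_wsi(sprintf("tile %s: stream fails %s signature check",
                     ifelse(is.na(index), "?", index), codec), "corrupt_tile")
  }
  invisible(TRUE)
}

#' An encoded tile stream
#'
#' Container for a self-contained entropy-coded tile, used by the transcode
#' path to move tiles between containers without decoding.
#'
#' @param index 1-based row-major tile index.
#' @param codec `"jpeg"` or `"jpeg2000"`.
#' @param stream Raw vector holding the self-contained codestream.
#' @return Object of class `wsi_encoded_tile`.
#' @export
encoded_tile <- function(index, codec, stream) {
  if (!codec %in% c("jpeg", "jpeg2000")) {
    stop_wsi("encoded tiles are only defined for jpeg and jpeg2000 streams",
             "invalid_parameter")
  }
  structure(list(index = as.integer(index), codec = codec, stream = stream),
            class = "wsi_encoded_tile")
}

#' @export
print.wsi_encoded_tile <- function(x, ...) {
  cat(sprintf("<wsi_encoded_tile> #%d %s, %d bytes\n",
              x$index, x$codec, length(x$stream)))
  invisible(x)
}
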