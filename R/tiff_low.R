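# Byte-level tiled TIFF container access (classic and BigTIFF), covering the
# subset of TIFF 6.0 + the tiling extension + the BigTIFF variant that slide
# containers use. Installed raster packages decode whole images only; the
# streaming engine needs per-tile random access and append-an-IFD writing,
# so the container layer is implemented here directly.
#
# Tags handled: 254 NewSubfileType, 256/257 size, 258 BitsPerSample,
# 259 Compression, 262 Photometric, 270 ImageDescription, 273/278/279 strips,
# 277 SamplesPerPixel, 282/283/296 resolution, 284 PlanarConfig,
# 305 Software, 317 Predictor, 322-325 tiles, 347 JPEGTables.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L, `13` = 4L, `16` = 8L, `17` = 8L,
                     `18` = 8L)

tiff_compression_to_codec <- function(code) {
  switch(as.character(code),
    `1` = "raw",
    `8` = "deflate", `32946` = "deflate",
    `7` = "jpeg",
    `34712` = "jpeg2000", `33003` = "jpeg2000", `33005` = "jpeg2000",
    NULL)
}

codec_to_tiff_compression <- function(codec) {
  switch(codec, raw = 1L, deflate = 8L, jpeg = 7L, jpeg2000 = 34712L)
}

# --- parsing ----------------------------------------------------------------

tiff_parse <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 8) {
    stop_wsi(sprintf("'%s' is not a TIFF file", path), "unsupported_format")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 16L)
  endian <- if (hdr[1] == as.raw(0x49)) "little" else "big"
  magic <- raw_to_int(hdr[3:4], 2, endian)
  if (magic == 42) {
    bigtiff <- FALSE
    ifd_off <- raw_to_int(hdr[5:8], 4, endian)
  } else if (magic == 43) {
    bigtiff <- TRUE
    ifd_off <- raw_to_int(hdr[9:16], 8, endian)
  } else {
    stop_wsi(sprintf("'%s' is not a TIFF file", path), "unsupported_format")
  }

  ifds <- list()
  while (ifd_off != 0) {
    if (ifd_off > sz) stop_wsi("corrupt TIFF: IFD offset beyond EOF", "corrupt_tile")
    seek(con, ifd_off)
    if (bigtiff) {
      n <- raw_to_int(readBin(con, "raw", 8L), 8, endian)
      entry_bytes <- readBin(con, "raw", n * 20L)
      next_ptr_pos <- ifd_off + 8 + n * 20
      next_off <- raw_to_int(readBin(con, "raw", 8L), 8, endian)
      esize <- 20L; inline <- 8L
    } else {
      n <- raw_to_int(readBin(con, "raw", 2L), 2, endian)
      entry_bytes <- readBin(con, "raw", n * 12L)
      next_ptr_pos <- ifd_off + 2 + n * 12
      next_off <- raw_to_int(readBin(con, "raw", 4L), 4, endian)
      esize <- 12L; inline <- 4L
    }
    tags <- list()
    for (i in seq_len(n)) {
      e <- entry_bytes[((i - 1L) * esize + 1L):(i * esize)]
      tag <- raw_to_int(e[1:2], 2, endian)
      type <- raw_to_int(e[3:4], 2, endian)
      if (bigtiff) {
        count <- raw_to_int(e[5:12], 8, endian)
        valfield <- e[13:20]
      } else {
        count <- raw_to_int(e[5:8], 4, endian)
        valfield <- e[9:12]
      }
      tsize <- TIFF_TYPE_SIZES[as.character(type)]
      if (is.na(tsize)) next
      total <- count * tsize
      if (total <= inline) {
        data <- valfield[seq_len(total)]
      } else {
        off <- raw_to_int(valfield, inline, endian)
        seek(con, off)
        data <- readBin(con, "raw", total)
      }
      tags[[as.character(tag)]] <- tiff_decode_value(data, type, endian)
    }
    ifds[[length(ifds) + 1L]] <- list(tags = tags, offset = ifd_off,
                                      next_ptr_pos = next_ptr_pos)
    ifd_off <- next_off
  }
  if (!length(ifds)) stop_wsi("TIFF contains no IFDs", "unsupported_format")
  list(path = path, endian = endian, bigtiff = bigtiff, ifds = ifds)
}

tiff_decode_value <- function(data, type, endian) {
  switch(as.character(type),
    `1` = , `6` = raw_to_int(data, 1, endian),
    `2` = {
      nul <- which(data == as.raw(0))
      end <- if (length(nul)) nul[1] - 1L else length(data)
      if (end > 0) rawToChar(data[seq_len(end)]) else ""
    },
    `3` = raw_to_int(data, 2, endian),
    `4` = , `13` = raw_to_int(data, 4, endian),
    `16` = , `17` = raw_to_int(data, 8, endian),
    `5` = {
      v <- raw_to_int(data, 4, endian)
      num <- v[seq(1, length(v), by = 2)]
      den <- v[seq(2, length(v), by = 2)]
      ifelse(den == 0, NA_real_, num / den)
    },
    `7` = data,
    data)
}

tiff_tag <- function(ifd, tag) ifd$tags[[as.character(tag)]]

tiff_is_tiled <- function(ifd) !is.null(tiff_tag(ifd, 322))

# Read the raw stored bytes of one tile (1-based row-major index).
tiff_read_tile_bytes <- function(path, ifd, tile_index) {
  offs <- tiff_tag(ifd, 324)
  cnts <- tiff_tag(ifd, 325)
  if (tile_index < 1 || tile_index > length(offs)) {
    stop_wsi(sprintf("tile index %d out of range 1..%d", tile_index, length(offs)),
             "bounds_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, offs[tile_index])
  readBin(con, "raw", cnts[tile_index])
}

# Merge a TIFF JPEGTables stream (tag 347) into an abbreviated tile stream so
# the result is a self-contained JFIF: tables segments are spliced in after
# the tile's SOI marker.
jpeg_merge_tables <- function(tables, stream) {
  if (is.null(tables) || length(tables) <= 4L) return(stream)
  tb <- tables
  n <- length(tb)
  # strip SOI (FFD8) head and EOI (FFD9) tail from the tables stream
  body <- tb[3:(n - 2L)]
  c(stream[1:2], body, stream[3:length(stream)])
}

# --- writing ----------------------------------------------------------------

# Streaming writer handle. Tiles/blocks are appended as they arrive; IFDs are
# written on finalize (and appended later for pyramid levels), keeping memory
# bounded by one tile.
tiff_writer_open <- function(path, bigtiff = FALSE, append = FALSE) {
  w <- new.env(parent = emptyenv())
  w$path <- path
  if (append) {
    p <- tiff_parse(path)
    w$bigtiff <- p$bigtiff
    if (p$endian != "little") {
      stop_wsi("can only append to little-endian TIFFs written by this package",
               "invalid_parameter")
    }
    w$chain_patch_pos <- p$ifds[[length(p$ifds)]]$next_ptr_pos
    w$con <- file(path, "r+b")
    seek(w$con, 0, origin = "end", rw = "write")
    w$pos <- file.size(path)
  } else {
    w$bigtiff <- bigtiff
    w$con <- file(path, "w+b")
    if (bigtiff) {
      writeBin(charToRaw("II"), w$con)
      writeBin(int_to_raw_le(c(43, 8, 0), 2), w$con)
      writeBin(int_to_raw_le(0, 8), w$con)
      w$chain_patch_pos <- 8
      w$pos <- 16
    } else {
      writeBin(charToRaw("II"), w$con)
      writeBin(int_to_raw_le(42, 2), w$con)
      writeBin(int_to_raw_le(0, 4), w$con)
      w$chain_patch_pos <- 4
      w$pos <- 8
    }
  }
  # abandoned writers (error paths) must not leak their connection; never
  # close twice — a stale connection object can alias a reused descriptor
  w$closed <- FALSE
  reg.finalizer(w, function(e) {
    if (!isTRUE(e$closed)) tryCatch(close(e$con), error = function(err) NULL)
  }, onexit = TRUE)
  w
}

tiff_writer_align <- function(w) {
  if (w$pos %% 2 == 1) {
    writeBin(as.raw(0), w$con)
    w$pos <- w$pos + 1
  }
}

# Append a data block, returning its file offset.
tiff_writer_put_block <- function(w, bytes) {
  tiff_writer_align(w)
  off <- w$pos
  writeBin(bytes, w$con)
  w$pos <- w$pos + length(bytes)
  off
}

# entries: list of list(tag=, type=, values=) with values numeric / character
# / raw according to type. Writes the IFD at EOF and links it into the chain.
tiff_writer_add_ifd <- function(w, entries) {
  tags <- vapply(entries, function(e) e$tag, numeric(1))
  entries <- entries[order(tags)]
  inline <- if (w$bigtiff) 8L else 4L
  esize <- if (w$bigtiff) 20L else 12L
  osize <- if (w$bigtiff) 8L else 4L

  enc <- lapply(entries, function(e) {
    vals <- e$values
    bytes <- switch(as.character(e$type),
      `2` = c(charToRaw(as.character(vals)), as.raw(0)),
      `3` = int_to_raw_le(vals, 2),
      `4` = int_to_raw_le(vals, 4),
      `5` = int_to_raw_le(as.vector(rbind(vals[c(TRUE, FALSE)],
                                          vals[c(FALSE, TRUE)])), 4),
      `7` = as.raw(vals),
      `16` = int_to_raw_le(vals, 8),
      `1` = as.raw(vals),
      stop_wsi(sprintf("unsupported TIFF entry type %s", e$type),
               "invalid_parameter"))
    count <- switch(as.character(e$type),
      `2` = length(bytes),
      `5` = length(vals) / 2,
      `7` = length(bytes),
      `1` = length(bytes),
      length(vals))
    list(tag = e$tag, type = e$type, count = count, bytes = bytes)
  })

  tiff_writer_align(w)
  ifd_off <- w$pos
  n <- length(enc)
  table_len <- (if (w$bigtiff) 8 else 2) + n * esize + osize
  data_off <- ifd_off + table_len

  # entry table
  tbl <- raw(0)
  extra <- raw(0)
  for (e in enc) {
    head <- c(int_to_raw_le(e$tag, 2), int_to_raw_le(e$type, 2),
              int_to_raw_le(e$count, if (w$bigtiff) 8 else 4))
    if (length(e$bytes) <= inline) {
      val <- c(e$bytes, raw(inline - length(e$bytes)))
    } else {
      off <- data_off + length(extra)
      if (off %% 2 == 1) {
        extra <- c(extra, as.raw(0))
        off <- off + 1
      }
      extra <- c(extra, e$bytes)
      val <- int_to_raw_le(off, inline)
    }
    tbl <- c(tbl, head, val)
  }
  count_bytes <- int_to_raw_le(n, if (w$bigtiff) 8 else 2)
  next_field <- int_to_raw_le(0, osize)
  block <- c(count_bytes, tbl, next_field, extra)
  writeBin(block, w$con)
  w$pos <- w$pos + length(block)

  # link into the IFD chain
  seek(w$con, w$chain_patch_pos, rw = "write")
  writeBin(int_to_raw_le(ifd_off, osize), w$con)
  seek(w$con, w$pos, rw = "write")
  w$chain_patch_pos <- ifd_off + (if (w$bigtiff) 8 else 2) + n * esize
  invisible(ifd_off)
}

tiff_writer_close <- function(w) {
  if (!isTRUE(w$closed)) {
    w$closed <- TRUE
    close(w$con)
  }
  invisible(w$path)
}

# Standard entry set for one tiled level.
tiff_level_entries <- function(geometry, codec, resolution = NULL,
                               offsets, bytecounts, description = NULL,
                               reduced = FALSE, bigtiff = FALSE) {
  off_type <- if (bigtiff) 16L else 4L
  photometric <- if (codec == "jpeg") 6L else 2L
  entries <- list(
    list(tag = 254, type = 4L, values = if (reduced) 1 else 0),
    list(tag = 256, type = 4L, values = geometry$width),
    list(tag = 257, type = 4L, values = geometry$height),
    list(tag = 258, type = 3L, values = c(8, 8, 8)),
    list(tag = 259, type = 3L, values = codec_to_tiff_compression(codec)),
    list(tag = 262, type = 3L, values = photometric),
    list(tag = 277, type = 3L, values = 3),
    list(tag = 284, type = 3L, values = 1),
    list(tag = 305, type = 2L, values = "wsiconvert"),
    list(tag = 322, type = 4L, values = geometry$tile_width),
    list(tag = 323, type = 4L, values = geometry$tile_height),
    list(tag = 324, type = off_type, values = offsets),
    list(tag = 325, type = 4L, values = bytecounts)
  )
  if (!is.null(description)) {
    entries <- c(entries, list(list(tag = 270, type = 2L, values = description)))
  }
  if (!is.null(resolution) && has_mpp(resolution)) {
    rx <- mpp_to_tiff_rational(resolution$mpp_x)
    ry <- mpp_to_tiff_rational(resolution$mpp_y)
    entries <- c(entries, list(
      list(tag = 282, type = 5L, values = rx),
      list(tag = 283, type = 5L, values = ry),
      list(tag = 296, type = 3L, values = 3)  # centimetre
    ))
  }
  entries
}

# Entry set for an untiled (single-strip) associated image, e.g. the SVS
# thumbnail stored as IFD 1.
tiff_strip_entries <- function(width, height, codec, offset, bytecount,
                               resolution = NULL) {
  entries <- list(
    list(tag = 256, type = 4L, values = width),
    list(tag = 257, type = 4L, values = height),
    list(tag = 258, type = 3L, values = c(8, 8, 8)),
    list(tag = 259, type = 3L, values = codec_to_tiff_compression(codec)),
    list(tag = 262, type = 3L, values = if (codec == "jpeg") 6L else 2L),
    list(tag = 273, type = 4L, values = offset),
    list(tag = 277, type = 3L, values = 3),
    list(tag = 278, type = 4L, values = height),
    list(tag = 279, type = 4L, values = bytecount),
    list(tag = 284, type = 3L, values = 1)
  )
  entries
}
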