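# DICOM whole-slide microscopy container access: single-file Part-10 objects,
# explicit VR little endian, encapsulated PixelData with one fragment per
# frame, dense row-major TILED_FULL frame layout. JPEG baseline
# (1.2.840.10008.1.2.4.50) and JPEG 2000 lossless (1.2.840.10008.1.2.4.90)
# transfer syntaxes are supported.

UID_SOP_CLASS_WSI <- "1.2.840.10008.5.1.4.1.1.77.1.6"
UID_TS_JPEG_BASELINE <- "1.2.840.10008.1.2.4.50"
UID_TS_J2K_LOSSLESS <- "1.2.840.10008.1.2.4.90"
UID_TS_J2K <- "1.2.840.10008.1.2.4.91"
UID_IMPLEMENTATION <- "2.25.72084396819707614048286275158786351559"

dicom_ts_to_codec <- function(uid) {
  switch(uid,
    "1.2.840.10008.1.2.4.50" = "jpeg",
    "1.2.840.10008.1.2.4.90" = "jpeg2000",
    "1.2.840.10008.1.2.4.91" = "jpeg2000",
    NULL)
}

# Deterministic UID generation: a 2.25-rooted UID from a small LCG so that a
# fixed seed yields byte-identical files (needed for reproducible output and
# the worker-count-independence contract). Seed NULL -> time/pid derived.
dicom_uid_generator <- function(seed = NULL) {
  if (is.null(seed)) {
    seed <- (as.integer(Sys.time()) %% 100000L) * 1000L + Sys.getpid() %% 1000L
  }
  state <- as.double(seed %% 2147483647L)
  if (state <= 0) state <- state + 2147483646
  function() {
    digits <- character(30L)
    for (i in 1:30) {
      state <<- (state * 48271) %% 2147483647
      digits[i] <- as.character(floor(state %% 10))
    }
    # no leading zero after the root
    paste0("2.25.", sub("^0+", "", paste(digits, collapse = "")))
  }
}

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")

dicom_enc_elem <- function(group, elem, vr, value_bytes) {
  n <- length(value_bytes)
  if (n %% 2 == 1) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" ")
    value_bytes <- c(value_bytes, pad)
    n <- n + 1L
  }
  head <- c(int_to_raw_le(group, 2), int_to_raw_le(elem, 2), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    c(head, raw(2), int_to_raw_le(n, 4), value_bytes)
  } else {
    c(head, int_to_raw_le(n, 2), value_bytes)
  }
}

dicom_enc_str <- function(group, elem, vr, s) {
  dicom_enc_elem(group, elem, vr, charToRaw(paste(s, collapse = "\\")))
}

dicom_enc_us <- function(group, elem, v) {
  dicom_enc_elem(group, elem, "US", int_to_raw_le(v, 2))
}

dicom_enc_ul <- function(group, elem, v) {
  dicom_enc_elem(group, elem, "UL", int_to_raw_le(v, 4))
}

dicom_ds_format <- function(x) sprintf("%.10g", x)

# SharedFunctionalGroupsSequence > PixelMeasuresSequence > PixelSpacing,
# all with undefined lengths and explicit delimiters.
dicom_enc_shared_groups <- function(spacing) {
  item_start <- c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE000, 2),
                  int_to_raw_le(0xFFFFFFFF, 4))
  item_delim <- c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE00D, 2), raw(4))
  seq_delim <- c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE0DD, 2), raw(4))
  ps <- dicom_enc_str(0x0028, 0x0030, "DS",
                      paste(dicom_ds_format(spacing), collapse = "\\"))
  inner_sq <- c(int_to_raw_le(0x0028, 2), int_to_raw_le(0x9110, 2),
                charToRaw("SQ"), raw(2), int_to_raw_le(0xFFFFFFFF, 4),
                item_start, ps, item_delim, seq_delim)
  c(int_to_raw_le(0x5200, 2), int_to_raw_le(0x9229, 2),
    charToRaw("SQ"), raw(2), int_to_raw_le(0xFFFFFFFF, 4),
    item_start, inner_sq, item_delim, seq_delim)
}

# Open a streaming DICOM writer: preamble, file meta, and the full dataset up
# to the PixelData element header and empty basic offset table are written
# immediately; frames are appended as encapsulated fragments.
dicom_writer_open <- function(path, geometry, resolution, codec, seed = NULL) {
  ts <- switch(codec, jpeg = UID_TS_JPEG_BASELINE,
               jpeg2000 = UID_TS_J2K_LOSSLESS,
               stop_wsi("DICOM supports only jpeg and jpeg2000 codecs",
                        "invalid_parameter"))
  gd <- tile_grid_dims(geometry)
  n_frames <- gd[1] * gd[2]
  uidgen <- dicom_uid_generator(seed)
  sop_uid <- uidgen()
  study_uid <- uidgen()
  series_uid <- uidgen()

  meta_body <- c(
    dicom_enc_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dicom_enc_str(0x0002, 0x0002, "UI", UID_SOP_CLASS_WSI),
    dicom_enc_str(0x0002, 0x0003, "UI", sop_uid),
    dicom_enc_str(0x0002, 0x0010, "UI", ts),
    dicom_enc_str(0x0002, 0x0012, "UI", UID_IMPLEMENTATION),
    dicom_enc_str(0x0002, 0x0013, "SH", "wsiconvert")
  )
  meta <- c(dicom_enc_ul(0x0002, 0x0000, length(meta_body)), meta_body)

  photometric <- if (codec == "jpeg") "YBR_FULL_422" else "RGB"
  ds <- c(
    dicom_enc_str(0x0008, 0x0016, "UI", UID_SOP_CLASS_WSI),
    dicom_enc_str(0x0008, 0x0018, "UI", sop_uid),
    dicom_enc_str(0x0008, 0x0060, "CS", "SM"),
    dicom_enc_str(0x0020, 0x000D, "UI", study_uid),
    dicom_enc_str(0x0020, 0x000E, "UI", series_uid),
    dicom_enc_str(0x0020, 0x9311, "CS", "TILED_FULL"),
    dicom_enc_us(0x0028, 0x0002, 3),
    dicom_enc_str(0x0028, 0x0004, "CS", photometric),
    dicom_enc_us(0x0028, 0x0006, 0),
    dicom_enc_str(0x0028, 0x0008, "IS", as.character(n_frames)),
    dicom_enc_us(0x0028, 0x0010, geometry$tile_height),
    dicom_enc_us(0x0028, 0x0011, geometry$tile_width),
    dicom_enc_us(0x0028, 0x0100, 8),
    dicom_enc_us(0x0028, 0x0101, 8),
    dicom_enc_us(0x0028, 0x0102, 7),
    dicom_enc_us(0x0028, 0x0103, 0),
    dicom_enc_ul(0x0048, 0x0006, geometry$width),
    dicom_enc_ul(0x0048, 0x0007, geometry$height)
  )
  spacing <- mpp_to_dicom_pixel_spacing(resolution)
  if (!is.null(spacing)) {
    ds <- c(ds, dicom_enc_shared_groups(spacing))
  }
  # encapsulated PixelData header + empty basic offset table
  ds <- c(ds,
          int_to_raw_le(0x7FE0, 2), int_to_raw_le(0x0010, 2),
          charToRaw("OB"), raw(2), int_to_raw_le(0xFFFFFFFF, 4),
          int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE000, 2), raw(4))

  con <- file(path, "wb")
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(ds, con)

  w <- new.env(parent = emptyenv())
  w$con <- con
  w$path <- path
  w$n_frames <- n_frames
  w$frames_written <- 0L
  w$bytes <- 132 + length(meta) + length(ds)
  w$closed <- FALSE
  reg.finalizer(w, function(e) {
    if (!isTRUE(e$closed)) tryCatch(close(e$con), error = function(err) NULL)
  }, onexit = TRUE)
  w
}

dicom_writer_put_frame <- function(w, stream) {
  n <- length(stream)
  pad <- n %% 2L
  writeBin(c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE000, 2),
             int_to_raw_le(n + pad, 4)), w$con)
  writeBin(stream, w$con)
  if (pad) writeBin(as.raw(0), w$con)
  w$frames_written <- w$frames_written + 1L
  w$bytes <- w$bytes + 8 + n + pad
  invisible(w)
}

dicom_writer_close <- function(w) {
  writeBin(c(int_to_raw_le(0xFFFE, 2), int_to_raw_le(0xE0DD, 2), raw(4)), w$con)
  w$closed <- TRUE
  close(w$con)
  invisible(w$path)
}

# --- parsing ----------------------------------------------------------------

dicom_is_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128)
  identical(readBin(con, "raw", 4L), charToRaw("DICM"))
}

dicom_read_elem_head <- function(con) {
  head <- readBin(con, "raw", 8L)
  if (length(head) < 8L) return(NULL)
  group <- raw_to_int(head[1:2], 2)
  elem <- raw_to_int(head[3:4], 2)
  if (group == 0xFFFE) {
    # delimitation items have no VR
    return(list(group = group, elem = elem,
                len = raw_to_int(head[5:8], 4), vr = NA_character_))
  }
  vr <- rawToChar(head[5:6])
  if (vr %in% DICOM_LONG_VRS) {
    len <- raw_to_int(readBin(con, "raw", 4L), 4)
  } else {
    len <- raw_to_int(head[7:8], 2)
  }
  list(group = group, elem = elem, vr = vr, len = len)
}

# Parse an explicit-VR-LE dataset from `con`, collecting primitive values
# into `acc` (an environment keyed "gggg,eeee"); descends into sequences.
# Stops after the PixelData element, recording fragment offsets.
dicom_parse_dataset <- function(con, acc, end_pos = Inf) {
  repeat {
    pos <- seek(con, NA)
    if (pos >= end_pos) return(invisible())
    h <- dicom_read_elem_head(con)
    if (is.null(h)) return(invisible())
    if (h$group == 0xFFFE) {
      if (h$elem %in% c(0xE00D, 0xE0DD)) return(invisible())  # delimiter
      # item inside an undefined-length sequence
      if (h$len == 0xFFFFFFFF) {
        dicom_parse_dataset(con, acc)
      } else {
        dicom_parse_dataset(con, acc, end_pos = seek(con, NA) + h$len)
      }
      next
    }
    key <- sprintf("%04X,%04X", h$group, h$elem)
    if (h$group == 0x7FE0 && h$elem == 0x0010) {
      acc$pixel_data <- dicom_parse_fragments(con, h)
      return(invisible())
    }
    if (identical(h$vr, "SQ")) {
      if (h$len == 0xFFFFFFFF) {
        dicom_parse_dataset(con, acc)
      } else {
        dicom_parse_dataset(con, acc, end_pos = seek(con, NA) + h$len)
      }
      next
    }
    if (h$len == 0xFFFFFFFF) {
      stop_wsi("unexpected undefined length on non-sequence element",
               "unsupported_format")
    }
    bytes <- readBin(con, "raw", h$len)
    acc[[key]] <- dicom_decode_value(bytes, h$vr)
  }
}

dicom_decode_value <- function(bytes, vr) {
  if (vr %in% c("UI", "CS", "SH", "LO", "IS", "DS", "LT", "AE", "PN")) {
    s <- rawToChar(bytes[bytes != as.raw(0)])
    s <- sub("\\s+$", "", s)
    if (vr %in% c("IS", "DS")) {
      return(as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]]))
    }
    return(s)
  }
  if (vr == "US") return(raw_to_int(bytes, 2))
  if (vr == "UL") return(raw_to_int(bytes, 4))
  bytes
}

dicom_parse_fragments <- function(con, head) {
  if (head$len != 0xFFFFFFFF) {
    stop_wsi("native (unencapsulated) DICOM pixel data not supported",
             "unsupported_modality")
  }
  # basic offset table
  bot <- dicom_read_elem_head(con)
  if (is.null(bot) || bot$group != 0xFFFE || bot$elem != 0xE000) {
    stop_wsi("malformed encapsulated pixel data (missing offset table)",
             "unsupported_format")
  }
  if (bot$len > 0) invisible(readBin(con, "raw", bot$len))
  offsets <- numeric(0)
  lengths <- numeric(0)
  repeat {
    h <- dicom_read_elem_head(con)
    if (is.null(h) || (h$group == 0xFFFE && h$elem == 0xE0DD)) break
    if (h$group != 0xFFFE || h$elem != 0xE000) {
      stop_wsi("malformed encapsulated pixel data", "unsupported_format")
    }
    offsets <- c(offsets, seek(con, NA))
    lengths <- c(lengths, h$len)
    seek(con, h$len, origin = "current")
  }
  list(offsets = offsets, lengths = lengths)
}

dicom_parse <- function(path) {
  if (!dicom_is_file(path)) {
    stop_wsi(sprintf("'%s' is not a DICOM file", path), "unsupported_format")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 132)
  h <- dicom_read_elem_head(con)
  if (is.null(h) || h$group != 0x0002 || h$elem != 0x0000) {
    stop_wsi("DICOM file meta group length missing", "unsupported_format")
  }
  glen <- raw_to_int(readBin(con, "raw", h$len), 4)
  meta_end <- seek(con, NA) + glen
  acc <- new.env(parent = emptyenv())
  dicom_parse_dataset(con, acc, end_pos = meta_end)
  ts <- acc[["0002,0010"]]
  if (is.null(ts)) stop_wsi("DICOM transfer syntax missing", "unsupported_format")
  codec <- dicom_ts_to_codec(ts)
  if (is.null(codec)) {
    stop_wsi(sprintf("unsupported DICOM transfer syntax %s", ts),
             "unsupported_modality")
  }
  seek(con, meta_end)
  dicom_parse_dataset(con, acc)
  out <- as.list(acc)
  out$path <- path
  out$codec <- codec
  out
}

dicom_read_frame_bytes <- function(parsed, i) {
  pd <- parsed$pixel_data
  if (i < 1 || i > length(pd$offsets)) {
    stop_wsi(sprintf("frame %d out of range 1..%d", i, length(pd$offsets)),
             "bounds_error")
  }
  con <- file(parsed$path, "rb")
  on.exit(close(con))
  seek(con, pd$offsets[i])
  bytes <- readBin(con, "raw", pd$lengths[i])
  # strip the even-length pad byte; both JFIF (EOI) and J2K (EOC) streams
  # end with the 0xFFD9 marker, so a trailing 0x00 after it is padding
  n <- length(bytes)
  if (n >= 3 && bytes[n] == as.raw(0) && bytes[n - 1L] == as.raw(0xD9) &&
      bytes[n - 2L] == as.raw(0xFF)) {
    bytes <- bytes[-n]
  }
  bytes
}
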