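# OME-NGFF v0.4 directory stores on a zarr v2 layout. The package writes
# arrays with shape (3, height, width), chunk shape (3, tile_h, tile_w),
# dtype uint8, C order, and a "." dimension separator; readers additionally
# accept (y, x, c) axis order and "/" separators. raw/zlib-compressed stores
# are interoperable with standard zarr tooling; the "jpeg" chunk compressor
# is this tool's own dialect (one JFIF stream per chunk).

ngff_compressor_json <- function(codec, quality) {
  switch(codec,
    raw = NULL,
    deflate = list(id = "zlib", level = 6L),
    jpeg = list(id = "jpeg", quality = as.integer(quality)),
    stop_wsi(sprintf("NGFF does not support codec '%s'", codec),
             "invalid_parameter"))
}

ngff_write_json <- function(x, path) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
}

ngff_zarray <- function(height, width, tile_h, tile_w, codec, quality) {
  list(
    zarr_format = 2L,
    shape = c(3L, as.integer(height), as.integer(width)),
    chunks = c(3L, as.integer(tile_h), as.integer(tile_w)),
    dtype = "|u1",
    compressor = ngff_compressor_json(codec, quality),
    fill_value = 255L,
    order = "C",
    filters = NULL,
    dimension_separator = "."
  )
}

ngff_axes <- function(with_unit) {
  space_axis <- function(name) {
    ax <- list(name = name, type = "space")
    if (with_unit) ax$unit <- "micrometer"
    ax
  }
  list(list(name = "c", type = "channel"), space_axis("y"), space_axis("x"))
}

# multiscales attrs for a list of levels: list(list(path=, downsample=), ...)
ngff_multiscales_attrs <- function(levels, resolution, name = "image") {
  with_unit <- has_mpp(resolution)
  datasets <- lapply(levels, function(lv) {
    sc <- mpp_to_ngff_scale(resolution, lv$downsample)
    list(path = lv$path,
         coordinateTransformations = list(list(type = "scale",
                                               scale = sc$scale)))
  })
  list(multiscales = list(list(
    version = "0.4",
    name = name,
    axes = ngff_axes(with_unit),
    datasets = datasets
  )))
}

ngff_chunk_key <- function(store, dataset, ci, yi, xi, sep = ".") {
  if (sep == "/") {
    file.path(store, dataset, ci, yi, as.character(xi))
  } else {
    file.path(store, dataset, paste(ci, yi, xi, sep = "."))
  }
}

# pixels: array c(h, w, 3) padded to full chunk shape -> chunk bytes,
# C order (c, y, x): x fastest.
ngff_chunk_encode <- function(pixels, codec, quality) {
  if (codec == "jpeg") {
    return(encode_tile(pixels, "jpeg", quality))
  }
  bytes <- as.raw(aperm(pixels, c(2L, 1L, 3L)))
  if (codec == "deflate") memCompress(bytes, type = "gzip") else bytes
}

ngff_chunk_decode <- function(bytes, compressor_id, chunk_shape, axes_order) {
  if (identical(compressor_id, "jpeg")) {
    hw <- if (axes_order == "cyx") chunk_shape[2:3] else chunk_shape[1:2]
    return(decode_tile(bytes, "jpeg", width = hw[2], height = hw[1]))
  }
  if (identical(compressor_id, "zlib") || identical(compressor_id, "gzip")) {
    bytes <- memDecompress(bytes, type = "gzip")
  }
  .wsi_state$decode_count <- .wsi_state$decode_count + 1L
  if (length(bytes) != prod(chunk_shape)) {
    stop_wsi(sprintf("chunk decodes to %d bytes, expected %d",
                     length(bytes), prod(chunk_shape)), "corrupt_tile")
  }
  if (axes_order == "cyx") {
    a <- array(as.integer(bytes), dim = rev(chunk_shape))  # (x, y, c)
    aperm(a, c(2L, 1L, 3L))
  } else {  # yxc, C order: c fastest
    a <- array(as.integer(bytes), dim = rev(chunk_shape))  # (c, x, y)
    aperm(a, c(3L, 2L, 1L))
  }
}

ngff_is_store <- function(path) {
  dir.exists(path) &&
    (file.exists(file.path(path, ".zattrs")) ||
       file.exists(file.path(path, ".zgroup")))
}

# Parse store metadata into level descriptors.
ngff_parse <- function(path) {
  attrs_path <- file.path(path, ".zattrs")
  if (!file.exists(attrs_path)) {
    stop_wsi(sprintf("'%s': no .zattrs; not an NGFF store", path),
             "unsupported_format")
  }
  attrs <- jsonlite::fromJSON(attrs_path, simplifyVector = FALSE)
  ms <- attrs$multiscales[[1]]
  if (is.null(ms)) {
    stop_wsi(sprintf("'%s': no multiscales metadata", path), "unsupported_format")
  }
  axis_names <- vapply(ms$axes, function(a) a$name, character(1))
  axes_order <- paste(axis_names, collapse = "")
  if (!axes_order %in% c("cyx", "yxc")) {
    stop_wsi(sprintf("unsupported NGFF axis order '%s'", axes_order),
             "unsupported_modality")
  }
  levels <- lapply(ms$datasets, function(ds) {
    za_path <- file.path(path, ds$path, ".zarray")
    za <- jsonlite::fromJSON(za_path, simplifyVector = TRUE)
    if (!identical(za$dtype, "|u1")) {
      stop_wsi(sprintf("NGFF dtype '%s' unsupported (8-bit RGB only)", za$dtype),
               "unsupported_modality")
    }
    shape <- as.integer(za$shape)
    chunks <- as.integer(za$chunks)
    if (axes_order == "cyx") {
      dims <- list(c = shape[1], h = shape[2], w = shape[3],
                   ch = chunks[2], cw = chunks[3])
    } else {
      dims <- list(c = shape[3], h = shape[1], w = shape[2],
                   ch = chunks[1], cw = chunks[2])
    }
    if (dims$c != 3L) {
      stop_wsi("NGFF store is not 3-channel RGB", "unsupported_modality")
    }
    scale <- NULL
    for (ct in ds$coordinateTransformations) {
      if (identical(ct$type, "scale")) scale <- unlist(ct$scale)
    }
    comp_id <- if (is.null(za$compressor)) NULL else za$compressor$id
    list(path = ds$path, shape = shape, chunks = chunks, dims = dims,
         compressor = comp_id,
         sep = za$dimension_separator %||% ".",
         scale = scale)
  })
  axes_units <- vapply(ms$axes, function(a) a$unit %||% NA_character_, character(1))
  list(path = path, axes_order = axes_order, levels = levels,
       axes_units = axes_units)
}

# Resolution from the level-0 scale transform (axes units micrometres).
ngff_resolution <- function(parsed) {
  lv0 <- parsed$levels[[1]]
  units <- parsed$axes_units
  if (is.null(lv0$scale)) return(resolution_info())
  if (parsed$axes_order == "cyx") {
    sy <- lv0$scale[2]; sx <- lv0$scale[3]
    uy <- units[2]; ux <- units[3]
  } else {
    sy <- lv0$scale[1]; sx <- lv0$scale[2]
    uy <- units[1]; ux <- units[2]
  }
  if (is.na(uy) || is.na(ux)) return(resolution_info())
  to_um <- c(micrometer = 1, nanometer = 1e-3, millimeter = 1e3)
  if (!ux %in% names(to_um) || !uy %in% names(to_um)) return(resolution_info())
  resolution_info(mpp_x = sx * to_um[[ux]], mpp_y = sy * to_um[[uy]])
}

ngff_read_chunk <- function(parsed, level, yi, xi) {
  lv <- parsed$levels[[level]]
  key <- if (parsed$axes_order == "cyx") {
    ngff_chunk_key(parsed$path, lv$path, 0L, yi, xi, lv$sep)
  } else {
    ngff_chunk_key(parsed$path, lv$path, yi, xi, 0L, lv$sep)
  }
  if (!file.exists(key)) {
    # zarr permits absent chunks meaning fill_value
    return(array(255L, dim = c(lv$dims$ch, lv$dims$cw, 3L)))
  }
  bytes <- readBin(key, "raw", file.size(key))
  ngff_chunk_decode(bytes, lv$compressor, lv$chunks, parsed$axes_order)
}
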