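# Internal helpers: error taxonomy, integer byte packing, small assertions.

# All package errors carry class c("wsi_<class>", "wsi_error", ...) so callers
# and the CLI can dispatch on failure kind.
stop_wsi <- function(message, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("wsi_", class), "wsi_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

warn_wsi <- function(message, class = "warning") {
  warning(structure(
    class = c(paste0("wsi_", class), "wsi_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}

ceil_div <- function(a, b) (a + b - 1L) %/% b

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

check_count <- function(x, name, min = 1) {
  if (!is_count(x, min)) {
    stop_wsi(sprintf("`%s` must be a single integer >= %s (got %s)",
                     name, min, deparse(x)[1]),
             "invalid_parameter")
  }
  as.integer(x)
}

# Pack non-negative numbers (doubles up to 2^53) into little-endian raw bytes.
# writeBin() cannot represent unsigned 32-bit values >= 2^31, so all TIFF/zarr
# integer fields go through this.
int_to_raw_le <- function(x, nbytes) {
  x <- as.double(x)
  out <- raw(length(x) * nbytes)
  for (i in seq_len(nbytes)) {
    out[seq(i, length(out), by = nbytes)] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# Inverse of int_to_raw_le; returns doubles (exact below 2^53).
raw_to_int <- function(bytes, nbytes, endian = "little", signed = FALSE) {
  m <- matrix(as.double(bytes), nrow = nbytes)
  weights <- 256^(0:(nbytes - 1))
  if (endian == "big") weights <- rev(weights)
  v <- as.vector(weights %*% m)
  if (signed) {
    lim <- 256^nbytes
    v <- ifelse(v >= lim / 2, v - lim, v)
  }
  v
}

# Round half up, elementwise; R's round() uses banker's rounding which is not
# what the pyramid contract specifies.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
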