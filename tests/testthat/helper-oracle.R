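# Shared test helpers: brute-force oracles kept deliberately independent of
# the implementation paths they check.

# Per-pixel regrid mapping: for every pixel of an n x n image, which read
# region and which write tile claims it; returns the unique (tile, region)
# dependency pairs, sorted. O(n^2) and loop-free.
brute_force_deps <- function(width, height, read_size, tile_size) {
  xs <- rep(0:(width - 1L), times = height)
  ys <- rep(0:(height - 1L), each = width)
  nrx <- ceiling(width / read_size)
  ntx <- ceiling(width / tile_size)
  region_id <- (ys %/% read_size) * nrx + xs %/% read_size + 1L
  tile_id <- (ys %/% tile_size) * ntx + xs %/% tile_size + 1L
  pairs <- unique(tile_id * 1e6 + region_id)
  sort(pairs)
}

plan_deps_pairs <- function(plan) {
  pairs <- unlist(lapply(seq_along(plan$deps), function(t) {
    t * 1e6 + plan$deps[[t]]
  }))
  sort(pairs)
}

# Direct f x f mean pooling (rounded half up), the reference for pyramid
# levels; trims the image to a multiple of f first when clip = TRUE.
mean_pool <- function(M, f) {
  h <- (nrow(M) %/% f) * f
  w <- (ncol(M) %/% f) * f
  M <- M[seq_len(h), seq_len(w), drop = FALSE]
  out <- matrix(0, h / f, w / f)
  for (i in seq_len(h / f)) {
    for (j in seq_len(w / f)) {
      out[i, j] <- floor(mean(M[((i - 1) * f + 1):(i * f),
                                ((j - 1) * f + 1):(j * f)]) + 0.5)
    }
  }
  out
}

tmp_path <- function(ext) {
  tempfile(fileext = ext)
}

# Smooth gradient block (no high-frequency content): the JPEG loss reference.
gradient_block <- function(w, h) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  arr <- array(0L, dim = c(h, w, 3))
  arr[, , 1] <- as.integer((X / w) * 255)
  arr[, , 2] <- as.integer((Y / h) * 255)
  arr[, , 3] <- as.integer(((X + Y) / (w + h)) * 255)
  arr
}

expect_wsi_error <- function(expr, class) {
  expect_error(expr, class = paste0("wsi_", class))
}

python_available <- function() {
  nzchar(Sys.which("python"))
}
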