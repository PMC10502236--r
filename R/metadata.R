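# Lossless translation of physical-resolution metadata (microns per pixel)
# between the container dialects:
#   * TIFF tags 282/283/296 (XResolution/YResolution as rationals, unit cm);
#   * the Aperio-style pipe-delimited ImageDescription string (SVS dialect);
#   * DICOM PixelSpacing (0028,0030) in millimetres, row (y) first;
#   * NGFF v0.4 multiscales coordinate scale transforms in micrometres.
# Unknown resolution is propagated as unknown, never defaulted.

#' Physical resolution of a slide
#'
#' @param mpp_x,mpp_y Microns per pixel along x and y (`NA` if unknown).
#' @param objective_power Optional nominal objective magnification (e.g. 20,
#'   40); carried through when present, never synthesised from mpp.
#' @return Object of class `wsi_resolution`.
#' @export
resolution_info <- function(mpp_x = NA_real_, mpp_y = mpp_x,
                            objective_power = NULL) {
  mpp_x <- as.double(mpp_x); mpp_y <- as.double(mpp_y)
  for (v in c(mpp_x, mpp_y)) {
    if (!is.na(v) && v <= 0) {
      stop_wsi("microns-per-pixel must be > 0 when present", "invalid_parameter")
    }
  }
  structure(list(mpp_x = mpp_x, mpp_y = mpp_y,
                 objective_power = if (is.null(objective_power)) NULL
                                   else as.double(objective_power)),
            class = "wsi_resolution")
}

has_mpp <- function(res) !is.null(res) && !is.na(res$mpp_x) && !is.na(res$mpp_y)

#' @export
print.wsi_resolution <- function(x, ...) {
  if (has_mpp(x)) {
    cat(sprintf("<wsi_resolution> %.6g x %.6g um/px%s\n", x$mpp_x, x$mpp_y,
                if (!is.null(x$objective_power))
                  sprintf(", objective %gx", x$objective_power) else ""))
  } else {
    cat("<wsi_resolution> unknown\n")
  }
  invisible(x)
}

MICRONS_PER_UNIT <- c(inch = 25400, centimeter = 10000)

#' Microns per pixel from TIFF resolution tags
#'
#' @param resolution_value Pixels per unit (TIFF XResolution/YResolution).
#' @param unit `"inch"`, `"centimeter"`, or `"none"` (unknown).
#' @return Microns per pixel, or `NA` when the tag pair carries no usable
#'   physical resolution (unit `"none"` or a non-positive value); no value is
#'   ever guessed.
#' @examples
#' mpp_from_tiff(40000, "centimeter")  # 0.25
#' mpp_from_tiff(25400, "inch")        # 1
#' @export
mpp_from_tiff <- function(resolution_value, unit = c("centimeter", "inch", "none")) {
  unit <- match.arg(unit)
  if (unit == "none" || is.na(resolution_value) || resolution_value <= 0) {
    return(NA_real_)
  }
  MICRONS_PER_UNIT[[unit]] / resolution_value
}

#' TIFF rational resolution value for a given mpp
#'
#' The TIFF writer always emits ResolutionUnit = centimeter with
#' X/YResolution = 10000/mpp pixels per cm as an unsigned rational. The
#' fraction is chosen exactly when `10^10 / (mpp * 10^6)` reduces to 32-bit
#' integers (true for all usual decimal mpp values), otherwise by the best
#' bounded approximation (relative error < 1e-9).
#'
#' @param mpp Microns per pixel.
#' @return `c(numerator, denominator)` for tags 282/283.
#' @export
mpp_to_tiff_rational <- function(mpp) {
  if (is.na(mpp) || mpp <= 0) {
    stop_wsi("mpp must be > 0", "invalid_parameter")
  }
  u32max <- 2^32 - 1
  # exact path: resolution = 1e4/mpp = 1e10 / (mpp * 1e6)
  p <- mpp * 1e6
  if (abs(p - round(p)) < 1e-9 * max(1, p)) {
    p <- round(p)
    g <- gcd_num(1e10, p)
    n <- 1e10 / g; d <- p / g
    if (n <= u32max && d <= u32max) return(c(n, d))
  }
  r <- 1e4 / mpp  # pixels per centimetre
  d <- min(1e6, floor(u32max / r))
  d <- max(1, d)
  c(round(r * d), d)
}

gcd_num <- function(a, b) {
  while (b > 0.5) {
    t <- a %% b; a <- b; b <- t
  }
  a
}

#' DICOM pixel spacing from resolution
#'
#' DICOM PixelSpacing is in millimetres and row-major: the first value is the
#' spacing between rows (y), the second between columns (x).
#'
#' @param res A [resolution_info()].
#' @return `c(row_spacing_mm, column_spacing_mm)`, or `NULL` (with a warning)
#'   when the resolution is unknown; the attribute is then omitted.
#' @examples
#' mpp_to_dicom_pixel_spacing(resolution_info(0.5, 0.25))  # c(0.00025, 5e-04)
#' @export
mpp_to_dicom_pixel_spacing <- function(res) {
  if (!has_mpp(res)) {
    warn_wsi("resolution unknown; PixelSpacing omitted", "missing_metadata")
    return(NULL)
  }
  c(res$mpp_y / 1000, res$mpp_x / 1000)
}

#' NGFF coordinate scale for a level
#'
#' @param res A [resolution_info()].
#' @param level_downsample Downsample factor of the level relative to level 0
#'   (>= 1).
#' @return List with `scale` (numeric length 3, axes c,y,x) and `unit`
#'   (`"micrometer"`, or `NULL` when resolution is unknown and the scale is
#'   the unitless `[1, 1, 1]`).
#' @export
mpp_to_ngff_scale <- function(res, level_downsample = 1) {
  if (!is.numeric(level_downsample) || level_downsample < 1) {
    stop_wsi("level_downsample must be >= 1", "invalid_parameter")
  }
  if (!has_mpp(res)) {
    return(list(scale = c(1, 1, 1), unit = NULL))
  }
  list(scale = c(1, res$mpp_y * level_downsample, res$mpp_x * level_downsample),
       unit = "micrometer")
}

#' Compose an Aperio-style SVS ImageDescription string
#'
#' @param res A [resolution_info()].
#' @param tool Short producer name placed at the head of the string.
#' @return The pipe-delimited description string.
#' @export
emit_svs_description <- function(res, tool = "wsiconvert") {
  parts <- sprintf("Aperio %s", tool)
  if (!is.null(res$objective_power)) {
    parts <- c(parts, sprintf("AppMag = %g", res$objective_power))
  }
  if (has_mpp(res)) {
    # SVS carries a single MPP; x is the canonical value
    parts <- c(parts, sprintf("MPP = %.10g", res$mpp_x))
  }
  paste(parts, collapse = "|")
}

#' Parse an Aperio-style SVS ImageDescription string
#'
#' Extracts `MPP = <float>` and `AppMag = <int>` from the pipe-delimited
#' description. Absent or malformed fields come back absent; this never
#' raises.
#'
#' @param description The ImageDescription text.
#' @return A [resolution_info()].
#' @examples
#' parse_svs_description("Aperio Fake |AppMag = 20|MPP = 0.4942")
#' @export
parse_svs_description <- function(description) {
  mpp <- NA_real_
  power <- NULL
  if (is.character(description) && length(description) == 1L && nzchar(description)) {
    fields <- strsplit(description, "|", fixed = TRUE)[[1]]
    for (f in fields) {
      kv <- regmatches(f, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.+?)\\s*$", f))[[1]]
      if (length(kv) != 3L) next
      key <- kv[2]; val <- suppressWarnings(as.numeric(kv[3]))
      if (is.na(val)) {
        if (key %in% c("MPP", "AppMag")) {
          warn_wsi(sprintf("malformed %s value in SVS description: %s", key, kv[3]),
                   "malformed_metadata")
        }
        next
      }
      if (key == "MPP" && val > 0) mpp <- val
      if (key == "AppMag") power <- val
    }
  }
  resolution_info(mpp_x = mpp, mpp_y = mpp, objective_power = power)
}
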