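# Reading and writing temperature matrices, coverage reports and run
# configuration.  Temperature images are plain numeric matrices in
# degrees Celsius, indexed (m = row, n = column), wrapped in a light
# "thermal_image" S3 class.

#' Construct a thermal image
#'
#' Wraps a numeric matrix of skin-surface temperatures (degrees C) and
#' validates it: all values must be finite and inside the plausible
#' thermal band \[0, 60\] degrees C, and the matrix must be at least
#' 8 x 8.
#'
#' @param values numeric matrix, temperatures in degrees C, indexed
#'   (row `m`, column `n`).
#' @param pixel_pitch_um optional detector pixel pitch in micrometers.
#' @param timestamp_s optional time since the last laser pulse, seconds.
#' @return A `thermal_image` object (a numeric matrix with attributes
#'   `pixel_pitch_um` and `timestamp_s`).
#' @export
thermal_image <- function(values, pixel_pitch_um = NA_real_, timestamp_s = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("thermal image values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 8L || ncol(values) < 8L)
    stop("thermal image must be at least 8 x 8 pixels", call. = FALSE)
  if (any(!is.finite(values)))
    stop("thermal image contains non-finite values", call. = FALSE)
  rng <- range(values)
  if (rng[1] < 0 || rng[2] > 60)
    stop(sprintf(
      "temperature out of the plausible band [0, 60] degrees C (extremum %.3f)",
      if (rng[1] < 0) rng[1] else rng[2]), call. = FALSE)
  structure(values,
            pixel_pitch_um = pixel_pitch_um,
            timestamp_s = timestamp_s,
            class = c("thermal_image", class(values)))
}

#' @export
print.thermal_image <- function(x, ...) {
  cat(sprintf("<thermal_image> %d x %d px, %.2f..%.2f degC\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# strip class/attributes, keep the bare matrix
img_values <- function(img) {
  m <- unclass(img)
  attr(m, "pixel_pitch_um") <- NULL
  attr(m, "timestamp_s") <- NULL
  m
}

#' Read a temperature matrix from CSV or float TIFF
#'
#' CSV files are headerless comma-separated numeric grids, one file row
#' per image row.  TIFF files must be single-channel rasters; 32-bit
#' IEEE-float TIFFs (as written by [write_thermal_image()]) carry the
#' temperatures verbatim.  No rescaling or resampling is applied on
#' load.
#'
#' @param path path to the file.
#' @param format `"csv"` or `"tiff"`; defaults to a guess from the file
#'   extension.
#' @inheritParams thermal_image
#' @return A [thermal_image()].
#' @export
read_thermal_image <- function(path, format = c("auto", "csv", "tiff"),
                               pixel_pitch_um = NA_real_, timestamp_s = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("cannot read thermal image: no such file '%s'", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  }
  values <- switch(format,
    csv = {
      dt <- data.table::fread(path, header = FALSE, sep = ",")
      m <- as.matrix(dt)
      dimnames(m) <- NULL
      if (!is.numeric(m))
        stop("CSV does not parse as a numeric matrix", call. = FALSE)
      m
    },
    tiff = {
      m <- tiff::readTIFF(path)
      if (length(dim(m)) != 2L)
        stop("TIFF is not a single-channel 2-D raster", call. = FALSE)
      m
    })
  thermal_image(values, pixel_pitch_um = pixel_pitch_um, timestamp_s = timestamp_s)
}

#' Write a temperature matrix to CSV or float TIFF
#'
#' CSV output uses `%.17g` formatting, which round-trips IEEE doubles
#' exactly.  TIFF output is a minimal uncompressed single-strip 32-bit
#' IEEE-float little-endian TIFF; temperatures are stored in degrees C
#' at single precision, so values already representable as 32-bit
#' floats round-trip bitwise.  (The float writer is implemented here
#' because the `tiff` package only writes integer sample formats
#' normalised to \[0, 1\].)
#'
#' @param img a [thermal_image()] or numeric matrix.
#' @param path output path.
#' @param format `"csv"` or `"tiff"`; defaults to a guess from the
#'   extension.
#' @return `path`, invisibly.
#' @export
write_thermal_image <- function(img, path, format = c("auto", "csv", "tiff")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "csv"
  }
  m <- img_values(img)
  if (format == "csv") {
    lines <- vapply(seq_len(nrow(m)), function(i)
      paste(sprintf("%.17g", m[i, ]), collapse = ","), character(1))
    writeLines(lines, path)
  } else {
    write_float_tiff(m, path)
  }
  invisible(path)
}

# Minimal single-channel 32-bit float TIFF writer (little-endian,
# uncompressed, one strip).  tiff::readTIFF reads it back verbatim.
write_float_tiff <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- ncol(m); h <- nrow(m)
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")         # offset of first IFD
  tags <- list(
    c(256L, 3L, 1L, w),                                  # ImageWidth
    c(257L, 3L, 1L, h),                                  # ImageLength
    c(258L, 3L, 1L, 32L),                                # BitsPerSample
    c(259L, 3L, 1L, 1L),                                 # Compression: none
    c(262L, 3L, 1L, 1L),                                 # Photometric: min-is-black
    c(273L, 4L, 1L, NA),                                 # StripOffsets (patched)
    c(277L, 3L, 1L, 1L),                                 # SamplesPerPixel
    c(278L, 3L, 1L, h),                                  # RowsPerStrip
    c(279L, 4L, 1L, w * h * 4L),                         # StripByteCounts
    c(339L, 3L, 1L, 3L))                                 # SampleFormat: IEEE float
  data_off <- 8L + 2L + length(tags) * 12L + 4L
  tags[[6]][4] <- data_off
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
  }
  writeBin(0L, con, size = 4, endian = "little")         # no further IFD
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
}

# ---------------------------------------------------------------------------
# Run configuration

#' Default run configuration
#'
#' Parameters of the analysis pipeline.  All sizes are in pixels at the
#' upsampled working resolution (default 480 x 640); temperatures are
#' in degrees C.
#'
#' @param binarization_threshold_pr constant binarization threshold
#'   `p_r` in degrees C, applied to the magnitude of the morphological
#'   difference image (an offset above the pre-treatment skin
#'   temperature).  `NA` (default) selects it automatically as
#'   `pr_auto_fraction` of the robust range of the difference image.
#' @param se_radius_px radius of the flat square structuring element of
#'   the grayscale opening; the element side is `2 * se_radius_px + 1`.
#'   It must exceed the whole treated field for the difference image to
#'   isolate the local temperature elevation.
#' @param canny_low,canny_high hysteresis thresholds for the Canny edge
#'   detector, expressed as quantiles (in `[0, 1)`) of the nonzero
#'   gradient magnitude inside the region of interest.
#' @param radon_angle_step_deg angular sampling step of the Radon
#'   transform, degrees.  A warning is recorded if it does not divide
#'   90 exactly.
#' @param upsample_to working resolution `(rows, cols)` of the
#'   nearest-neighbour upsampling.
#' @param median_mask odd `(rows, cols)` dimensions of the median
#'   filter mask.
#' @param analysis_window_s `(min_s, max_s)` validity window for the
#'   time since the last pulse, seconds.
#' @param connectivity pixel connectivity (4 or 8) used for labelling.
#' @param difference_polarity `"opening_abs"` forms the difference
#'   image from the grayscale opening, `"closing_abs"` from the
#'   grayscale closing; in both cases the binarized quantity is the
#'   absolute difference from the median-filtered image.
#' @param roi_bridge_px radius of the binary closing applied to the
#'   binarized image before labelling, so that one treated field with
#'   narrow cool gaps labels as a single cluster.  0 disables it.
#' @param roi_fill_holes fill interior holes of the selected largest
#'   cluster, so that untreated islands inside the field stay part of
#'   the region of interest.
#' @param watershed_h minimum prominence (degrees C) of a regional
#'   maximum for it to seed a watershed basin (h-maxima suppression).
#' @param detrend_method how the constant temperature component is
#'   eliminated before watershed segmentation: `"constant"` subtracts
#'   the mean over the region of interest, `"local"` a grayscale
#'   opening background (see [remove_constant_component()]).
#' @param detrend_se_radius_px background-opening radius for
#'   `detrend_method = "local"`; should exceed half the pulse pitch.
#' @param pulse_side_px side length of one pulse footprint in working
#'   pixels, if known from the laser head geometry and camera optics;
#'   `NA` estimates it from the segmented footprints instead.
#' @param canny_sigma Gaussian presmoothing sigma of the Canny
#'   detector, pixels.
#' @param pr_auto_fraction,pr_auto_quantile automatic threshold rule:
#'   `p_r = pr_auto_fraction * (quantile(|L_U|, pr_auto_quantile) -
#'   median(|L_U|))`.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(binarization_threshold_pr = NA_real_,
                           se_radius_px = 80L,
                           canny_low = 0.40,
                           canny_high = 0.80,
                           radon_angle_step_deg = 0.5,
                           upsample_to = c(480L, 640L),
                           median_mask = c(3L, 3L),
                           analysis_window_s = c(10, 180),
                           connectivity = 8L,
                           difference_polarity = c("opening_abs", "closing_abs"),
                           roi_bridge_px = 5L,
                           roi_fill_holes = TRUE,
                           watershed_h = 0.3,
                           detrend_method = c("constant", "local"),
                           detrend_se_radius_px = 40L,
                           pulse_side_px = NA_real_,
                           canny_sigma = 1.4,
                           pr_auto_fraction = 0.4,
                           pr_auto_quantile = 0.995) {
  cfg <- list(
    binarization_threshold_pr = binarization_threshold_pr,
    se_radius_px = as.integer(se_radius_px),
    canny_low = canny_low,
    canny_high = canny_high,
    radon_angle_step_deg = radon_angle_step_deg,
    upsample_to = as.integer(upsample_to),
    median_mask = as.integer(median_mask),
    analysis_window_s = as.numeric(analysis_window_s),
    connectivity = as.integer(connectivity),
    difference_polarity = match.arg(difference_polarity),
    roi_bridge_px = as.integer(roi_bridge_px),
    roi_fill_holes = isTRUE(roi_fill_holes),
    watershed_h = watershed_h,
    detrend_method = match.arg(detrend_method),
    detrend_se_radius_px = as.integer(detrend_se_radius_px),
    pulse_side_px = pulse_side_px,
    canny_sigma = canny_sigma,
    pr_auto_fraction = pr_auto_fraction,
    pr_auto_quantile = pr_auto_quantile)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$analysis_window_s[1] >= cfg$analysis_window_s[2])
    stop("analysis window requires min_s < max_s", call. = FALSE)
  if (any(cfg$upsample_to < 8L) || cfg$se_radius_px < 1L ||
      any(cfg$median_mask < 1L) || cfg$radon_angle_step_deg <= 0)
    stop("all configuration sizes must be positive", call. = FALSE)
  if (any(cfg$median_mask %% 2L == 0L))
    stop("median filter mask dimensions must be odd", call. = FALSE)
  if (!cfg$connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  if (cfg$canny_high <= cfg$canny_low || cfg$canny_low < 0)
    stop("canny thresholds require high > low >= 0", call. = FALSE)
  if (abs(90 / cfg$radon_angle_step_deg -
          round(90 / cfg$radon_angle_step_deg)) > 1e-9)
    warning("radon_angle_step_deg does not divide 90 exactly", call. = FALSE)
  cfg
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file holds any subset of the fields of [default_config()];
#' missing fields take their defaults.
#'
#' @param path path to the YAML (or JSON) configuration file.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such configuration file '%s'", path), call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(default_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(default_config, vals)
}

# ---------------------------------------------------------------------------
# Coverage report serialisation

# run-length encoding of a logical matrix (column-major), as a compact
# "length:value" string, e.g. "12:0,5:1,..."
rle_encode_mask <- function(mask) {
  r <- rle(as.integer(mask))
  paste(sprintf("%d:%d", r$lengths, r$values), collapse = ",")
}

rle_decode_mask <- function(s, shape) {
  if (s == "") return(matrix(FALSE, shape[1], shape[2]))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  lens <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  vals <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  v <- inverse.rle(structure(list(lengths = lens, values = vals), class = "rle"))
  matrix(as.logical(v), shape[1], shape[2])
}

#' Write a coverage report to JSON
#'
#' Percentages are rounded to two decimals in the JSON body; the exact
#' integer pixel counts they derive from are stored alongside, and the
#' uncovered/overlap masks are stored as run-length-encoded strings.
#' The serialisation is deterministic: writing, re-reading and writing
#' again produces identical bytes.
#'
#' @param report a `coverage_report` from [analyze_image()].
#' @param path output path of the JSON document.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "coverage_report"))
  doc <- list(
    delta_o_percent = round(report$delta_o_percent, 2),
    delta_z_percent = round(report$delta_z_percent, 2),
    n_pulses = report$n_pulses,
    angle_deg = report$angle_deg,
    threshold_pr = report$threshold_pr,
    pixel_counts = report$pixel_counts,
    mask_shape = dim(report$uncovered_mask),
    uncovered_mask_rle = rle_encode_mask(report$uncovered_mask),
    overlap_mask_rle = rle_encode_mask(report$overlap_mask),
    config = unclass(report$config_echo))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read back a coverage report written by [write_report()]
#'
#' @param path path to the JSON report.
#' @return A `coverage_report` with the masks reconstructed from their
#'   run-length encoding.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(doc$mask_shape)
  cfg <- doc$config
  cfg$difference_polarity <- as.character(cfg$difference_polarity)
  cfg <- do.call(default_config, cfg)
  structure(list(
    delta_o_percent = doc$delta_o_percent,
    delta_z_percent = doc$delta_z_percent,
    n_pulses = as.integer(doc$n_pulses),
    angle_deg = doc$angle_deg,
    threshold_pr = doc$threshold_pr,
    pixel_counts = lapply(doc$pixel_counts, as.integer),
    uncovered_mask = rle_decode_mask(doc$uncovered_mask_rle, shape),
    overlap_mask = rle_decode_mask(doc$overlap_mask_rle, shape),
    config_echo = cfg), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> delta_o = %.2f%%, delta_z = %.2f%%, %d pulses, grid angle %.1f deg (p_r = %.3f degC)\n",
    x$delta_o_percent, x$delta_z_percent, x$n_pulses, x$angle_deg, x$threshold_pr))
  invisible(x)
}
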