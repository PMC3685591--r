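# Coverage errors.  Both metrics are pixel counts with respect to the
# whole treated region L_R: delta_o is the percentage of its pixels
# covered by zero pulse footprints (undertreatment), delta_z the
# percentage covered by two or more footprints (double dose).  The
# per-pixel coverage-count formulation reduces to the
# inclusion-exclusion form |L_R| - sum_i |L_i| + |L_Z| in the pairwise
# case and stays exact when three or more footprints superimpose.

pulse_mask_list <- function(pulses) {
  lapply(pulses, function(p) {
    if (inherits(p, "pulse_area")) p$mask else p
  })
}

# integer per-pixel coverage counts of a list of pulse masks
coverage_count_matrix <- function(pulses, shape) {
  counts <- matrix(0L, shape[1], shape[2])
  for (m in pulse_mask_list(pulses)) {
    stopifnot(identical(dim(m), shape))
    counts <- counts + m
  }
  counts
}

#' Overlap mask of a set of pulse areas
#'
#' A pixel belongs to the overlap mask iff it lies in at least two
#' pulse footprints.
#'
#' @param pulses list of `pulse_area` objects or logical masks.
#' @param shape `(rows, cols)` of the masks.
#' @return An `overlap_mask`: list with `mask` (logical) and
#'   `n_pixels`.
#' @export
build_overlap_mask <- function(pulses, shape) {
  if (length(pulses) == 0L) stop("at least one pulse area required", call. = FALSE)
  counts <- coverage_count_matrix(pulses, shape)
  mask <- counts >= 2L
  structure(list(mask = mask, n_pixels = sum(mask)), class = "overlap_mask")
}

#' Undertreatment error delta_o
#'
#' Percentage of treated-region pixels covered by zero pulse
#' footprints.  Footprints are clipped to the region before counting,
#' and each covered pixel is counted once regardless of multiplicity,
#' which generalises the inclusion-exclusion count
#' `(|L_R| - sum_i |L_i| + |L_Z|) / |L_R|` beyond pairwise overlaps.
#'
#' @param roi a `roi_mask` (non-empty).
#' @param pulses list of `pulse_area` objects or logical masks.
#' @param overlap optional precomputed [build_overlap_mask()] result
#'   (unused by the count-based formulation; accepted for symmetry).
#' @return delta_o in percent, with the exact pixel counts in the
#'   `"pixel_counts"` attribute.
#' @export
delta_o <- function(roi, pulses, overlap = NULL) {
  if (roi$n_pixels == 0L) stop("empty region of interest", call. = FALSE)
  counts <- coverage_count_matrix(pulses, dim(roi$mask))
  n_roi <- roi$n_pixels
  n_unc <- sum(roi$mask & counts == 0L)
  structure(100 * n_unc / n_roi,
            pixel_counts = c(roi = n_roi, uncovered = n_unc))
}

#' Double-dose error delta_z
#'
#' Percentage of treated-region pixels lying in the overlap mask, i.e.
#' covered by two or more footprints.  The denominator is the whole
#' treated region `|L_R|`.
#'
#' @param roi a `roi_mask` (non-empty).
#' @param overlap an [build_overlap_mask()] result (or logical mask).
#' @return delta_z in percent, with the exact pixel counts in the
#'   `"pixel_counts"` attribute.
#' @export
delta_z <- function(roi, overlap) {
  if (roi$n_pixels == 0L) stop("empty region of interest", call. = FALSE)
  m <- if (inherits(overlap, "overlap_mask")) overlap$mask else overlap
  n_roi <- roi$n_pixels
  n_z <- sum(roi$mask & m)
  structure(100 * n_z / n_roi,
            pixel_counts = c(roi = n_roi, overlap = n_z))
}

#' Full two-stage analysis of one thermogram
#'
#' Runs [extract_roi()], estimates the grid angle from the Radon
#' transform of the Canny edges, segments pulse footprints by
#' watershed, approximates them by rotated squares, and counts the
#' coverage errors.  The fitted squares are clipped to the binarized
#' elevation evidence (a square only counts as dose where the skin is
#' actually elevated above `p_r`) and to the region of interest.  The
#' analysis is deterministic: the same image and configuration always
#' produce the same report.
#'
#' @param img a [thermal_image()].
#' @param config a [default_config()].
#' @return A `coverage_report`: `delta_o_percent`, `delta_z_percent`,
#'   `n_pulses`, `angle_deg`, `threshold_pr`, `uncovered_mask`,
#'   `overlap_mask`, an exact `pixel_counts` ledger, `config_echo`,
#'   and (not serialised) the `roi`, `pulses` and intermediate `stack`.
#' @export
analyze_image <- function(img, config = default_config()) {
  config <- validate_config(config)
  stage <- "roi"
  res <- tryCatch({
    pre <- extract_roi(img, config)
    stage <- "angle"
    edges <- canny_edges(pre$stack$l_med, pre$roi,
                         low = config$canny_low, high = config$canny_high,
                         sigma = config$canny_sigma)
    sino <- radon_transform(edges, config$radon_angle_step_deg)
    ang <- as.numeric(estimate_grid_angle(sino))
    stage <- "watershed"
    det <- remove_constant_component(pre$stack$l_med, pre$roi,
                                     method = config$detrend_method,
                                     se_radius_px = config$detrend_se_radius_px)
    labs <- watershed_pulses(det, pre$roi, h = config$watershed_h)
    stage <- "fit"
    pulses <- fit_squares(labs, det, ang, config)
    stage <- "coverage"
    eff <- lapply(pulses, function(p) p$mask & pre$stack$l_b & pre$roi$mask)
    counts <- coverage_count_matrix(eff, dim(pre$roi$mask))
    uncovered <- pre$roi$mask & counts == 0L
    overlap <- pre$roi$mask & counts >= 2L
    n_roi <- pre$roi$n_pixels
    ledger <- list(roi = n_roi,
                   uncovered = sum(uncovered),
                   single = sum(pre$roi$mask & counts == 1L),
                   multi = sum(overlap))
    stopifnot(ledger$uncovered + ledger$single + ledger$multi == ledger$roi)
    structure(list(
      delta_o_percent = 100 * ledger$uncovered / n_roi,
      delta_z_percent = 100 * ledger$multi / n_roi,
      n_pulses = length(pulses),
      angle_deg = ang,
      threshold_pr = pre$stack$p_r,
      pixel_counts = ledger,
      uncovered_mask = uncovered,
      overlap_mask = overlap,
      config_echo = config,
      roi = pre$roi,
      pulses = pulses,
      stack = pre$stack), class = "coverage_report")
  }, error = function(e) {
    stop(sprintf("analysis failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Sensitivity of delta_o to the binarization threshold
#'
#' Repeats the coverage measurement of [analyze_image()] for a range of
#' binarization thresholds and tabulates the resulting errors.  The
#' treated region and the fitted pulse geometry are established once,
#' at the reference configuration; each swept `p_r` then re-binarizes
#' the elevation evidence that the fitted squares are clipped to.
#' Because the binarized sets are nested in `p_r`, the uncovered
#' percentage is nondecreasing in the threshold — and on typical scenes
#' it grows almost linearly over the mid-range of the elevation
#' distribution, which is why no single threshold is unequivocally
#' correct and why the footprint segmentation itself relies on
#' watershed rather than on thresholding.
#'
#' When a swept threshold equals the configuration's own threshold the
#' row reproduces [analyze_image()]'s errors exactly.  A threshold
#' whose measurement fails is recorded as a missing row rather than
#' aborting the sweep.
#'
#' @param img a [thermal_image()].
#' @param config a [default_config()].
#' @param pr_values increasing thresholds, degrees C; `NULL` picks an
#'   8-point sweep between the 20% and 80% quantiles of the difference
#'   magnitude inside the detected region (the mid-range of the
#'   elevation distribution).
#' @return A data frame with columns `p_r`, `delta_o`, `delta_z`,
#'   `n_pulses` (one row per threshold, `NA` where the measurement
#'   failed).
#' @export
threshold_sweep <- function(img, config = default_config(), pr_values = NULL) {
  config <- validate_config(config)
  base <- analyze_image(img, config)
  mag <- abs(base$stack$l_u)
  if (is.null(pr_values)) {
    v <- mag[base$roi$mask]
    pr_values <- seq(quantile(v, 0.2, names = FALSE),
                     quantile(v, 0.8, names = FALSE), length.out = 8)
  }
  if (length(pr_values) < 1L || is.unsorted(pr_values, strictly = TRUE))
    stop("pr_values must be strictly increasing", call. = FALSE)
  rows <- lapply(pr_values, function(pr) {
    row <- tryCatch({
      l_b <- binarize(mag, pr)
      eff <- lapply(base$pulses, function(p) p$mask & l_b & base$roi$mask)
      counts <- coverage_count_matrix(eff, dim(base$roi$mask))
      data.frame(p_r = pr,
                 delta_o = 100 * sum(base$roi$mask & counts == 0L) / base$roi$n_pixels,
                 delta_z = 100 * sum(base$roi$mask & counts >= 2L) / base$roi$n_pixels,
                 n_pulses = length(base$pulses))
    }, error = function(e) NULL)
    if (is.null(row))
      row <- data.frame(p_r = pr, delta_o = NA_real_, delta_z = NA_real_,
                        n_pulses = NA_integer_)
    row
  })
  do.call(rbind, rows)
}
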