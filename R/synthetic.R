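# Synthetic thermogram generator.  Emulates the thermal signature of a
# fractional-laser treatment field: baseline skin at about 33 degC,
# square pulse footprints elevated by about 2.5 degC, a Gaussian-beam
# fluence profile inside each footprint, a broad diffusion mound under
# the whole field, first-order step response in time, and i.i.d.
# Gaussian sensor noise.  Every scene carries pixel-exact ground-truth
# masks so downstream stages can be validated without patient data.

#' Describe a synthetic treatment scene
#'
#' @param pulses data frame with columns `center_row`, `center_col`,
#'   `side_px`, `angle_deg` — one row per laser pulse.  All pulses
#'   share one angle (the head is applied without rotation between
#'   pulses) and sides must be at least 4 px.
#' @param roi_polygon matrix with columns `(row, col)`: vertices of the
#'   treated-region polygon used as ground-truth region of interest.
#' @param frame `(rows, cols)` of the generated image; the default
#'   matches the analysis working resolution so ground-truth masks
#'   align with the pipeline output pixel for pixel.
#' @param baseline_temp_c pre-treatment skin temperature, degrees C.
#' @param elevation_c steady-state temperature elevation of a pulse
#'   footprint above baseline, degrees C.
#' @param noise_sd_c standard deviation of i.i.d. Gaussian sensor
#'   noise, degrees C.
#' @param tau_s first-order time constant of the skin step response,
#'   seconds.
#' @param seed integer seed; a fixed seed makes generation bit-for-bit
#'   reproducible.
#' @param beam_sigma_px Gaussian blur sigma (px) of each footprint
#'   edge, emulating the bell-shaped fluence of the laser beam; 0 gives
#'   hard square plateaus.
#' @param mound_amp_c,mound_sigma_px amplitude (degrees C) and blur
#'   sigma (px) of the broad warm mound produced by lateral heat
#'   diffusion under the whole treated field; `mound_amp_c = 0`
#'   disables it.
#' @param decay_tau_s optional slow exponential decay of the elevation
#'   toward baseline (thermoregulation); `Inf` (default) disables it,
#'   matching the observation that footprints persist for at least 20
#'   minutes.
#' @return A `synthetic_scene` list.
#' @seealso [scene_grid()] for the usual regular-grid construction.
#' @export
synthetic_scene <- function(pulses,
                            roi_polygon,
                            frame = c(480L, 640L),
                            baseline_temp_c = 33,
                            elevation_c = 2.5,
                            noise_sd_c = 0.05,
                            tau_s = 1.5,
                            seed = 1L,
                            beam_sigma_px = 5,
                            mound_amp_c = 1.5,
                            mound_sigma_px = 8,
                            decay_tau_s = Inf) {
  pulses <- as.data.frame(pulses)
  if (nrow(pulses) > 0) {
    need <- c("center_row", "center_col", "side_px", "angle_deg")
    if (!all(need %in% names(pulses)))
      stop("pulses must have columns ", paste(need, collapse = ", "), call. = FALSE)
    if (length(unique(pulses$angle_deg)) > 1L)
      stop("all pulse squares must share one angle", call. = FALSE)
    if (any(pulses$side_px < 4))
      stop("pulse side must be at least 4 px", call. = FALSE)
    rad <- pulses$side_px / 2 * sqrt(2)
    if (any(pulses$center_row - rad < 1 | pulses$center_row + rad > frame[1] |
            pulses$center_col - rad < 1 | pulses$center_col + rad > frame[2]))
      stop("pulse placement error: a pulse square extends outside the frame",
           call. = FALSE)
  }
  if (elevation_c <= 0) stop("elevation_c must be positive", call. = FALSE)
  if (noise_sd_c < 0) stop("noise_sd_c must be nonnegative", call. = FALSE)
  structure(list(
    pulses = pulses, roi_polygon = roi_polygon, frame = as.integer(frame),
    baseline_temp_c = baseline_temp_c, elevation_c = elevation_c,
    noise_sd_c = noise_sd_c, tau_s = tau_s, seed = as.integer(seed),
    beam_sigma_px = beam_sigma_px, mound_amp_c = mound_amp_c,
    mound_sigma_px = mound_sigma_px, decay_tau_s = decay_tau_s),
    class = "synthetic_scene")
}

#' Regular pulse grid scene
#'
#' Places `grid_rows x grid_cols` square pulses of side `side_px` on a
#' regular grid with the given center-to-center pitch, rotates the
#' whole grid by `angle_deg` about the frame center, and takes the
#' rotated grid bounding rectangle (expanded by `margin_px`) as the
#' ground-truth treated region.  A pitch above `side_px` leaves
#' untreated gaps between footprints (undertreatment); a pitch below
#' `side_px` makes neighbouring footprints overlap (double dose).
#'
#' @param grid_rows,grid_cols grid dimensions.
#' @param side_px pulse footprint side, px.
#' @param pitch_px center-to-center spacing, px; scalar or
#'   `(row_pitch, col_pitch)`.
#' @param row_offsets,col_offsets optional explicit center offsets (px,
#'   in the grid's own frame) overriding the regular pitch along that
#'   axis — e.g. an irregular column spacing that makes one pair of
#'   columns overlap.
#' @param angle_deg common rotation of the grid and of every square.
#' @param margin_px extra border of the ground-truth region around the
#'   outermost footprints, px.
#' @param center `(row, col)` grid center; defaults to the frame center.
#' @inheritParams synthetic_scene
#' @param ... further arguments passed to [synthetic_scene()].
#' @return A `synthetic_scene`.
#' @export
scene_grid <- function(grid_rows = 3L, grid_cols = 4L, side_px = 30,
                       pitch_px = 34, angle_deg = 12, margin_px = 2,
                       frame = c(480L, 640L), center = NULL,
                       row_offsets = NULL, col_offsets = NULL, ...) {
  if (length(pitch_px) == 1L) pitch_px <- c(pitch_px, pitch_px)
  if (is.null(center)) center <- (frame + 1) / 2
  gi <- if (is.null(row_offsets)) {
    (seq_len(grid_rows) - (grid_rows + 1) / 2) * pitch_px[1]
  } else row_offsets - mean(row_offsets)
  gj <- if (is.null(col_offsets)) {
    (seq_len(grid_cols) - (grid_cols + 1) / 2) * pitch_px[2]
  } else col_offsets - mean(col_offsets)
  g <- expand.grid(dv = gi, du = gj)
  # grid offsets live in the grid's own (v, u) frame; map to image offsets
  co <- cospi(angle_deg / 180); si <- sinpi(angle_deg / 180)
  dr <- co * g$dv + si * g$du
  dc <- -si * g$dv + co * g$du
  pulses <- data.frame(center_row = center[1] + dr,
                       center_col = center[2] + dc,
                       side_px = side_px, angle_deg = angle_deg)
  hv <- diff(range(gi)) / 2 + side_px / 2 + margin_px
  hu <- diff(range(gj)) / 2 + side_px / 2 + margin_px
  corners_v <- c(-hv, -hv, hv, hv)
  corners_u <- c(-hu, hu, hu, -hu)
  poly <- cbind(row = center[1] + co * corners_v + si * corners_u,
                col = center[2] - si * corners_v + co * corners_u)
  synthetic_scene(pulses = pulses, roi_polygon = poly, frame = frame,
                  ...)
}

# steady-state elevation field (degC above baseline) of a scene:
# saturating (max) composition of per-pulse Gaussian-beam footprints
# plus an additive diffusion mound under the treated field.
scene_elevation_field <- function(scene) {
  shape <- scene$frame
  elev <- matrix(0, shape[1], shape[2])
  p <- scene$pulses
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      f <- blurred_rect_field(c(p$center_row[i], p$center_col[i]),
                              p$side_px[i] / 2, p$side_px[i] / 2,
                              p$angle_deg[i], scene$beam_sigma_px, shape)
      elev <- pmax(elev, f)
    }
    elev <- scene$elevation_c * elev
    if (scene$mound_amp_c > 0) {
      roi <- rasterize_polygon(scene$roi_polygon, shape)
      mound <- gaussian_blur(roi * 1.0, scene$mound_sigma_px)
      elev <- elev + scene$mound_amp_c * mound
    }
  }
  elev
}

# ground-truth masks and coverage errors by direct pixel counting
scene_ground_truth <- function(scene) {
  shape <- scene$frame
  p <- scene$pulses
  pulse_masks <- lapply(seq_len(nrow(p)), function(i)
    rasterize_square(c(p$center_row[i], p$center_col[i]),
                     p$side_px[i], p$angle_deg[i], shape))
  counts <- matrix(0L, shape[1], shape[2])
  for (m in pulse_masks) counts <- counts + m
  roi_mask <- if (is.null(scene$roi_polygon)) {
    matrix(FALSE, shape[1], shape[2])
  } else {
    rasterize_polygon(scene$roi_polygon, shape)
  }
  union_mask <- counts >= 1L
  overlap_mask <- counts >= 2L
  n_roi <- sum(roi_mask)
  if (n_roi > 0) {
    true_do <- 100 * sum(roi_mask & counts == 0L) / n_roi
    true_dz <- 100 * sum(roi_mask & overlap_mask) / n_roi
  } else {
    true_do <- NA_real_
    true_dz <- NA_real_
  }
  structure(list(pulse_masks = pulse_masks, union_mask = union_mask,
                 overlap_mask = overlap_mask, roi_mask = roi_mask,
                 coverage_counts = counts,
                 true_delta_o_percent = true_do,
                 true_delta_z_percent = true_dz),
            class = "ground_truth")
}

#' Generate a synthetic thermogram and its ground truth
#'
#' Renders the steady-state image `baseline + elevation field + noise`
#' of a scene.  The ground-truth masks reflect the exact geometric
#' squares before beam blur and noise; the true coverage errors are
#' obtained by direct pixel counting on those masks (uncovered = in the
#' region but in no square; overlapping = in at least two squares).
#' When the ground-truth region is empty the true errors are undefined
#' and returned as `NA`.
#'
#' @param scene a [synthetic_scene()].
#' @return A list with elements `image` (a [thermal_image()]) and
#'   `truth` (a `ground_truth` with `pulse_masks`, `union_mask`,
#'   `overlap_mask`, `roi_mask`, `coverage_counts`,
#'   `true_delta_o_percent`, `true_delta_z_percent`).
#' @export
generate_scene <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  shape <- scene$frame
  elev <- scene_elevation_field(scene)
  values <- scene$baseline_temp_c + elev
  if (scene$noise_sd_c > 0) {
    set.seed(scene$seed)
    values <- values + matrix(rnorm(length(values), 0, scene$noise_sd_c),
                              shape[1], shape[2])
  }
  list(image = thermal_image(values),
       truth = scene_ground_truth(scene))
}

#' Generate a frame sequence with first-order step response
#'
#' Each pixel follows `T(t) = baseline + E * (1 - exp(-t / tau))`,
#' where `E` is the pixel's steady-state elevation: the first-order
#' inertia response of skin to the laser forcing.  Temperatures are
#' nondecreasing in time and approach `baseline + E` asymptotically
#' (unless the optional slow decay is enabled via `decay_tau_s`).
#'
#' @param scene a [synthetic_scene()]; `scene$tau_s` must be positive.
#' @param frame_times_s increasing, nonnegative times (seconds since
#'   the forcing) at which frames are rendered.
#' @return A list of [thermal_image()]s, one per time, each carrying
#'   its time in the `timestamp_s` attribute.
#' @export
generate_sequence <- function(scene, frame_times_s) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (scene$tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  if (length(frame_times_s) == 0 || any(frame_times_s < 0) ||
      is.unsorted(frame_times_s, strictly = FALSE))
    stop("frame_times_s must be nonnegative and increasing", call. = FALSE)
  shape <- scene$frame
  elev <- scene_elevation_field(scene)
  if (scene$noise_sd_c > 0) set.seed(scene$seed)
  lapply(frame_times_s, function(t) {
    fct <- (1 - exp(-t / scene$tau_s))
    if (is.finite(scene$decay_tau_s)) fct <- fct * exp(-t / scene$decay_tau_s)
    values <- scene$baseline_temp_c + fct * elev
    if (scene$noise_sd_c > 0)
      values <- values + matrix(rnorm(length(values), 0, scene$noise_sd_c),
                                shape[1], shape[2])
    thermal_image(values, timestamp_s = t)
  })
}

#' Check that a thermogram falls inside the analysis validity window
#'
#' The footprint shape is only a faithful proxy of the irradiated area
#' once the first-order skin response has settled (no sooner than 10 s
#' after the last dose) and before thermoregulation blurs it (no later
#' than a few minutes).
#'
#' @param t_since_last_pulse_s nonnegative time since the last
#'   irradiation dose, seconds.
#' @param config a [default_config()]; the window is
#'   `config$analysis_window_s` (closed interval).
#' @return A list with `valid` (logical) and `reason` (string).
#' @export
check_analysis_window <- function(t_since_last_pulse_s, config = default_config()) {
  stopifnot(t_since_last_pulse_s >= 0)
  w <- config$analysis_window_s
  if (t_since_last_pulse_s < w[1]) {
    list(valid = FALSE, reason = "before thermal steady state")
  } else if (t_since_last_pulse_s > w[2]) {
    list(valid = FALSE, reason = "footprint decayed by thermoregulation")
  } else {
    list(valid = TRUE, reason = "within analysis window")
  }
}
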