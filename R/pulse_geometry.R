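# Stage two: recover the pulse-grid geometry inside the treated
# region.  Canny edges of the footprint boundaries -> Radon transform
# -> common grid angle -> marker-controlled watershed -> rotated-square
# approximation of each footprint.

# shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Canny edge detection restricted to the treated region
#'
#' Standard Canny: Gaussian presmoothing, Sobel gradient, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' thresholding.  The hysteresis thresholds are quantiles (`low`,
#' `high`) of the nonzero gradient magnitude inside the (dilated)
#' region of interest, so they adapt to the thermal contrast of the
#' scene.  Edges outside the dilated region are discarded.
#'
#' @param img image or matrix (typically the median-filtered working
#'   image).
#' @param roi a `roi_mask` from [extract_roi()].
#' @param low,high quantile thresholds, `high > low >= 0`.
#' @param sigma presmoothing sigma, px.
#' @return A logical edge mask of the image shape (class
#'   `edge_image`).
#' @export
canny_edges <- function(img, roi, low = 0.40, high = 0.80, sigma = 1.4) {
  if (high <= low || low < 0) stop("canny thresholds require high > low >= 0", call. = FALSE)
  m <- img_values(img)
  stopifnot(identical(dim(m), dim(roi$mask)))
  band <- minmax_filter_cpp(roi$mask * 1.0, 3L, 3L, TRUE) > 0.5  # dilated ROI
  sm <- gaussian_blur(m, sigma)
  gx <- (shift_mat(sm, 0, 1) - shift_mat(sm, 0, -1)) +
    0.5 * (shift_mat(sm, 1, 1) - shift_mat(sm, 1, -1)) +
    0.5 * (shift_mat(sm, -1, 1) - shift_mat(sm, -1, -1))
  gy <- (shift_mat(sm, 1, 0) - shift_mat(sm, -1, 0)) +
    0.5 * (shift_mat(sm, 1, 1) - shift_mat(sm, -1, 1)) +
    0.5 * (shift_mat(sm, 1, -1) - shift_mat(sm, -1, -1))
  mag <- sqrt(gx^2 + gy^2)
  inside <- band & mag > 0
  if (!any(inside)) {
    warning("constant region of interest: no edges found", call. = FALSE)
    return(structure(matrix(FALSE, nrow(m), ncol(m)), class = "edge_image"))
  }
  # non-maximum suppression: quantize direction to 4 sectors
  ang <- atan2(gy, gx)                 # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L),       # horizontal gradient -> compare left/right
                "1" = c(1L, 1L),
                "2" = c(1L, 0L),
                "3" = c(1L, -1L))
    sel <- sector == s
    n1[sel] <- shift_mat(mag, d[1], d[2])[sel]
    n2[sel] <- shift_mat(mag, -d[1], -d[2])[sel]
  }
  nms <- mag >= n1 & mag >= n2 & mag > 0
  vals <- mag[inside]
  tl <- quantile(vals, low, names = FALSE)
  th <- quantile(vals, high, names = FALSE)
  weak <- nms & mag > tl & band
  strong <- weak & mag >= th
  if (!any(strong)) {
    warning("no strong edges above the high threshold", call. = FALSE)
    return(structure(matrix(FALSE, nrow(m), ncol(m)), class = "edge_image"))
  }
  lab <- label_components(weak, 8L)
  keep <- sort(unique(lab[strong]))
  edges <- matrix(lab %in% keep, nrow(m), ncol(m)) & weak
  structure(edges, class = "edge_image")
}

#' Radon transform of a binary edge image
#'
#' Line-integral projections of the edge mask over angles sampled on
#' `[0, 90)` degrees.  Each edge pixel at centered offset `(m, n)`
#' contributes one count to the projection bin
#' `n' = round(n cos(alpha) + m sin(alpha))`, so the total mass of
#' every angle column equals the number of edge pixels exactly.
#'
#' @param edges logical edge mask (from [canny_edges()]).
#' @param angle_step_deg angular sampling step, degrees.
#' @return A `radon_sinogram`: list with `values` (offsets x angles
#'   count matrix), `angles_deg`, `offsets`, `n_edge_pixels`.
#' @export
radon_transform <- function(edges, angle_step_deg = 0.5) {
  idx <- which(img_values(edges) != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no edges for angle estimation", call. = FALSE)
  angles <- seq(0, 90 - angle_step_deg, by = angle_step_deg)
  mr <- idx[, 1] - mean(idx[, 1])
  nc <- idx[, 2] - mean(idx[, 2])
  rmax <- ceiling(max(sqrt(mr^2 + nc^2))) + 1L
  offsets <- (-rmax):rmax
  values <- matrix(0L, length(offsets), length(angles))
  for (k in seq_along(angles)) {
    co <- cospi(angles[k] / 180); si <- sinpi(angles[k] / 180)
    np <- round(nc * co + mr * si)
    values[, k] <- tabulate(np + rmax + 1L, nbins = length(offsets))
  }
  structure(list(values = values, angles_deg = angles, offsets = offsets,
                 n_edge_pixels = nrow(idx)), class = "radon_sinogram")
}

#' Estimate the common grid angle from a sinogram
#'
#' The pulse squares share one rotation angle; edge segments of the
#' grid are collinear, so the projection taken along their direction
#' concentrates many edge pixels into single bins.  The angle score is
#' the maximum single-bin count of each sinogram column and the
#' estimate is the arg-max angle; since a square grid is 90-degree
#' symmetric the angle is reported in `[0, 90)`.  Ties are broken
#' toward the smallest angle.
#'
#' @param sinogram a `radon_sinogram`.
#' @return The angle estimate in degrees, with the per-angle scores in
#'   the `"scores"` attribute.
#' @export
estimate_grid_angle <- function(sinogram) {
  stopifnot(inherits(sinogram, "radon_sinogram"))
  scores <- apply(sinogram$values, 2, max)
  if (diff(range(scores)) == 0)
    stop("angle not identifiable: no dominant direction", call. = FALSE)
  est <- sinogram$angles_deg[which.max(scores)] %% 90
  structure(est, scores = setNames(scores, sinogram$angles_deg))
}

#' Rotate an image or mask by the negative of an angle
#'
#' Nearest-neighbour resampling about a center (default: the matrix
#' center), so binary masks stay binary.  `derotate(x, a)` undoes
#' `derotate(x, -a)` up to resampling error.  Pixels mapped from
#' outside the frame take the fill value.
#'
#' @param x numeric or logical matrix.
#' @param angle_deg angle to remove, degrees.
#' @param center `(row, col)` rotation center.
#' @param fill fill value for pixels from outside the frame (default 0,
#'   i.e. `FALSE` for masks).
#' @return Matrix of the same shape and type.
#' @export
derotate <- function(x, angle_deg, center = NULL, fill = 0) {
  m <- img_values(x)
  logical_in <- is.logical(m)
  if (is.null(center)) center <- (dim(m) + 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  dr <- matrix(seq_len(nr) - center[1], nr, nc)
  dc <- matrix(seq_len(nc) - center[2], nr, nc, byrow = TRUE)
  # output pixel (r,c) samples the input at the +angle rotated offset
  rc <- rotate_offsets(dr, dc, -angle_deg)
  sr <- round(center[1] + rc$v)
  sc <- round(center[2] + rc$u)
  ok <- sr >= 1 & sr <= nr & sc >= 1 & sc <= nc
  out <- matrix(rep(fill, nr * nc), nr, nc)
  out[ok] <- m[cbind(sr[ok], sc[ok])]
  if (logical_in) out <- out > 0.5
  out
}

#' Remove the constant temperature component over the treated region
#'
#' With `method = "constant"` subtracts the mean temperature of the
#' region of interest, leaving the pulse-relative topography: the
#' output has exactly zero mean over the region, is invariant to a
#' global temperature offset, and preserves relative peak heights.
#' With `method = "local"` subtracts a smooth background estimate (the
#' grayscale opening with a square element of radius `se_radius_px`,
#' which tracks the slowly varying diffusion warmth under the field but
#' not the pulse bumps themselves); this removes the background tilt
#' that would otherwise bias footprint centroids near the field
#' boundary.  Pixels outside the region are set to zero in both cases.
#'
#' @param img image or matrix.
#' @param roi a `roi_mask`.
#' @param method `"constant"` or `"local"` (see above).
#' @param se_radius_px background-opening radius for `method =
#'   "local"`; should exceed half the pulse pitch so whole footprints
#'   are removed from the background estimate.
#' @return A detrended matrix (zero outside the region).
#' @export
remove_constant_component <- function(img, roi, method = c("constant", "local"),
                                      se_radius_px = 40L) {
  method <- match.arg(method)
  m <- img_values(img)
  stopifnot(identical(dim(m), dim(roi$mask)))
  if (roi$n_pixels == 0L) stop("empty region of interest", call. = FALSE)
  out <- if (method == "constant") {
    m - mean(m[roi$mask])
  } else {
    m - morphological_open(m, se_radius_px)
  }
  out[!roi$mask] <- 0
  out
}

#' Watershed segmentation of pulse footprints
#'
#' Marker-controlled watershed on the detrended temperature topography:
#' markers are the regional maxima that survive h-maxima suppression at
#' prominence `h` (so sensor noise and small overlap ridges do not
#' seed basins), and flooding partitions the region of interest into
#' one labelled basin per candidate pulse.
#'
#' @param detrended matrix from [remove_constant_component()].
#' @param roi a `roi_mask`.
#' @param h minimum prominence of a marker, degrees C.
#' @return Integer label matrix; labels `1..K` partition the region of
#'   interest exactly, 0 is background.
#' @export
watershed_pulses <- function(detrended, roi, h = 0.3) {
  m <- img_values(detrended)
  stopifnot(identical(dim(m), dim(roi$mask)))
  if (roi$n_pixels == 0L) stop("empty region of interest", call. = FALSE)
  x <- m - min(m[roi$mask]) + 1e-6
  x[!roi$mask] <- 0
  lab <- EBImage::watershed(x, tolerance = h, ext = 1L)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (max(lab) == 0L) stop("no pulses detected", call. = FALSE)
  lab
}

#' Approximate labelled footprints by rotated squares
#'
#' Each label becomes one pulse area: the center is the
#' intensity-weighted centroid of the label's upper half (pixels whose
#' detrended value exceeds the midpoint between the label's minimum and
#' maximum, which for a blurred plateau sits at the plateau boundary);
#' all pulses share the side length — taken from
#' `config$pulse_side_px` when the head footprint is known from the
#' laser geometry, otherwise the median over labels of the square root
#' of the upper-half area — and the common grid angle.  Labels whose
#' area falls outside `[0.25, 4]` times the median label area are
#' discarded as spurious.
#'
#' @param labels integer label matrix from [watershed_pulses()].
#' @param detrended matrix from [remove_constant_component()].
#' @param angle_deg common grid angle, degrees.
#' @param config a [default_config()].
#' @return List of `pulse_area` objects (fields `center`, `side_px`,
#'   `angle_deg`, `mask`), with the indices of discarded labels in the
#'   `"discarded"` attribute.
#' @export
fit_squares <- function(labels, detrended, angle_deg, config = default_config()) {
  det <- img_values(detrended)
  shape <- dim(det)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) stop("no valid pulse areas", call. = FALSE)
  areas <- tabulate(labels[labels > 0L])[ids]
  med_area <- median(areas)
  keep <- areas >= 0.25 * med_area & areas <= 4 * med_area
  discarded <- ids[!keep]
  ids <- ids[keep]
  if (length(ids) == 0L) stop("no valid pulse areas", call. = FALSE)
  cores <- vector("list", length(ids))
  centers <- matrix(NA_real_, length(ids), 2)
  for (i in seq_along(ids)) {
    px <- which(labels == ids[i])
    v <- det[px]
    core <- px[v >= (min(v) + max(v)) / 2]
    w <- det[core] - min(v)
    if (sum(w) <= 0) w <- rep(1, length(core))
    rowc <- (core - 1L) %% shape[1] + 1L
    colc <- (core - 1L) %/% shape[1] + 1L
    centers[i, ] <- c(sum(w * rowc) / sum(w), sum(w * colc) / sum(w))
    cores[[i]] <- core
  }
  side <- config$pulse_side_px
  if (is.na(side))
    side <- median(sqrt(vapply(cores, length, numeric(1))))
  centers <- refine_centers(det, centers, halfwin = ceiling(0.55 * side))
  pulses <- lapply(seq_along(ids), function(i) {
    structure(list(center = centers[i, ],
                   side_px = side,
                   angle_deg = angle_deg,
                   mask = rasterize_square(centers[i, ], side, angle_deg, shape)),
              class = "pulse_area")
  })
  attr(pulses, "discarded") <- discarded
  pulses
}

# Iterative refinement of footprint centers.  The watershed basin of a
# boundary pulse is asymmetric and the diffusion warmth under the field
# tilts its intensity, both of which bias the basin centroid toward
# the field interior by 1-2 px.  Re-estimating each center as the
# weighted centroid of the upper half of the detrended intensity over
# a symmetric window, after subtracting the least-squares plane of the
# window (the local background tilt; the symmetric footprint bump
# contributes nothing to the plane slope), removes both biases.
refine_centers <- function(det, centers, halfwin, iters = 3L) {
  shape <- dim(det)
  for (it in seq_len(iters)) {
    centers <- t(apply(centers, 1, function(ce) {
      r0 <- max(1L, round(ce[1]) - halfwin); r1 <- min(shape[1], round(ce[1]) + halfwin)
      c0 <- max(1L, round(ce[2]) - halfwin); c1 <- min(shape[2], round(ce[2]) + halfwin)
      win <- det[r0:r1, c0:c1, drop = FALSE]
      rr <- matrix(r0:r1, nrow(win), ncol(win))
      cc <- matrix(c0:c1, nrow(win), ncol(win), byrow = TRUE)
      dr <- rr - mean(r0:r1); dc <- cc - mean(c0:c1)
      win <- win - sum(win * dr) / sum(dr^2) * dr - sum(win * dc) / sum(dc^2) * dc
      w <- pmax(win - min(win) - 0.5 * (max(win) - min(win)), 0)
      if (sum(w) <= 0) return(ce)
      c(sum(w * rr) / sum(w), sum(w * cc) / sum(w))
    }))
  }
  centers
}

#' @export
print.pulse_area <- function(x, ...) {
  cat(sprintf("<pulse_area> center (%.1f, %.1f), side %.1f px, angle %.1f deg\n",
              x$center[1], x$center[2], x$side_px, x$angle_deg))
  invisible(x)
}
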