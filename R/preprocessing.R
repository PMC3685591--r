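# Stage one: from a raw thermogram to the treated-region mask.
# upsample -> median filter -> grayscale opening -> difference image
# -> binarization at p_r -> labelling -> largest cluster.

#' Nearest-neighbour upsampling
#'
#' Increases resolution without inventing pixel values: every output
#' pixel copies the nearest input pixel, so the output value set is a
#' subset of the input value set.
#'
#' @param img [thermal_image()] or numeric matrix.
#' @param target `(rows, cols)`; must be at least the source size in
#'   both dimensions.
#' @return A [thermal_image()] of the target size.
#' @export
upsample_nearest <- function(img, target = c(480L, 640L)) {
  m <- img_values(img)
  target <- as.integer(target)
  if (target[1] < nrow(m) || target[2] < ncol(m))
    stop("upsampling target must be at least the source size", call. = FALSE)
  ri <- floor((seq_len(target[1]) - 1L) * nrow(m) / target[1]) + 1L
  ci <- floor((seq_len(target[2]) - 1L) * ncol(m) / target[2]) + 1L
  # values are unchanged, so the input's validation carries over
  structure(m[ri, ci, drop = FALSE],
            pixel_pitch_um = attr(img, "pixel_pitch_um"),
            timestamp_s = attr(img, "timestamp_s"),
            class = c("thermal_image", "matrix", "array"))
}

#' Median filter
#'
#' Each output pixel is the median of its `mask` neighbourhood; the
#' border is handled by edge replication.
#'
#' @param img [thermal_image()] or numeric matrix.
#' @param mask odd `(rows, cols)` window dimensions.
#' @return Filtered image of the same kind as the input values (a bare
#'   matrix).
#' @export
median_filter <- function(img, mask = c(3L, 3L)) {
  mask <- as.integer(mask)
  if (any(mask %% 2L == 0L) || any(mask < 1L))
    stop("median mask dimensions must be odd and positive", call. = FALSE)
  median_filter_cpp(img_values(img), mask[1], mask[2])
}

# flat erosion / dilation with a square structuring element of radius r
gray_erode <- function(m, r) minmax_filter_cpp(m, r, r, FALSE)
gray_dilate <- function(m, r) minmax_filter_cpp(m, r, r, TRUE)

#' Grayscale morphological opening
#'
#' Flat opening `max_SE(min_SE(img))` (erosion followed by dilation)
#' with a square structuring element of side `2 * se_radius_px + 1`.
#' The opening is anti-extensive (output <= input everywhere) and
#' idempotent; with an element larger than the treated field it
#' removes the field entirely and leaves the background, so the
#' difference from the input isolates the local temperature elevation.
#'
#' @param img image or matrix.
#' @param se_radius_px radius of the square element, px.
#' @return Opened matrix.
#' @export
morphological_open <- function(img, se_radius_px) {
  m <- img_values(img)
  r <- as.integer(se_radius_px)
  if (r < 1L) stop("structuring element must be non-empty", call. = FALSE)
  if (2L * r + 1L > min(dim(m)))
    stop("structuring element larger than the image", call. = FALSE)
  gray_dilate(gray_erode(m, r), r)
}

#' Grayscale morphological closing
#'
#' Flat closing (dilation followed by erosion); extensive counterpart
#' of [morphological_open()], used by the `"closing_abs"` difference
#' polarity.
#'
#' @inheritParams morphological_open
#' @return Closed matrix.
#' @export
morphological_close <- function(img, se_radius_px) {
  m <- img_values(img)
  r <- as.integer(se_radius_px)
  if (r < 1L) stop("structuring element must be non-empty", call. = FALSE)
  if (2L * r + 1L > min(dim(m)))
    stop("structuring element larger than the image", call. = FALSE)
  gray_erode(gray_dilate(m, r), r)
}

#' Elementwise difference image
#'
#' `l_a - l_b`, signed values retained.
#'
#' @param l_a,l_b matrices of identical shape.
#' @return The signed difference matrix.
#' @export
difference_image <- function(l_a, l_b) {
  a <- img_values(l_a); b <- img_values(l_b)
  if (!identical(dim(a), dim(b)))
    stop("difference_image: shape mismatch", call. = FALSE)
  a - b
}

#' Binarize at a constant threshold
#'
#' Strict comparison: a pixel is true iff its value exceeds `p_r`.
#'
#' @param l_u numeric matrix (typically the magnitude of the
#'   difference image, i.e. the temperature elevation above the local
#'   background).
#' @param p_r finite threshold, degrees C.
#' @return Logical matrix.
#' @export
binarize <- function(l_u, p_r) {
  if (!is.finite(p_r)) stop("threshold p_r must be finite", call. = FALSE)
  img_values(l_u) > p_r
}

#' Label connected components
#'
#' Deterministic labelling (components numbered in raster-scan order of
#' their first pixel).
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels, 0 = background.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  label_components_cpp(mask, as.integer(connectivity))
}

roi_mask_new <- function(mask) {
  n <- sum(mask)
  bbox <- if (n > 0L) {
    idx <- which(mask, arr.ind = TRUE)
    c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  } else {
    rep(NA_integer_, 4)
  }
  structure(list(mask = mask, n_pixels = n, bounding_box = bbox),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px, bbox rows %d..%d cols %d..%d\n",
              x$n_pixels, x$bounding_box[1], x$bounding_box[3],
              x$bounding_box[2], x$bounding_box[4]))
  invisible(x)
}

#' Keep the largest connected component
#'
#' Labels the binary image and returns the component with the largest
#' pixel count; ties are broken deterministically by the smallest
#' bounding-box `(row0, col0)`.
#'
#' @param l_b logical matrix with at least one true pixel.
#' @param connectivity 4 or 8.
#' @return A `roi_mask` (fields `mask`, `n_pixels`, `bounding_box`).
#' @export
largest_component_roi <- function(l_b, connectivity = 8L) {
  if (!any(l_b)) stop("no treated region detected", call. = FALSE)
  lab <- label_components(l_b, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: smallest (row0, col0) of the bounding box
    key <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      min(idx[, 1]) * (ncol(l_b) + 1) + min(idx[, 2])
    }, numeric(1))
    best <- best[which.min(key)]
  }
  roi_mask_new(lab == best)
}

# binary closing used to bridge narrow cool gaps between footprints
binary_close <- function(mask, r) {
  if (r < 1L) return(mask)
  minmax_filter_cpp(minmax_filter_cpp(mask * 1.0, r, r, TRUE), r, r, FALSE) > 0.5
}

# automatic threshold: fraction of the robust range of the difference
# magnitude above its (background-dominated) median
auto_threshold_pr <- function(mag, config) {
  q <- quantile(mag, config$pr_auto_quantile, names = FALSE)
  config$pr_auto_fraction * (q - median(mag))
}

#' Extract the treated-region mask from a thermogram
#'
#' Runs the full first stage: nearest-neighbour upsampling to the
#' working resolution, median filtering, grayscale opening (or closing)
#' with a large structuring element, difference image, binarization of
#' the absolute difference at `p_r`, binary closing to bridge narrow
#' inter-pulse gaps, labelling with selection of the largest cluster,
#' and hole filling so that untreated islands inside the field remain
#' part of the region of interest.
#'
#' @param img a [thermal_image()] at camera or working resolution.
#' @param config a [default_config()].
#' @return A list with `roi` (a `roi_mask`) and `stack` (the
#'   intermediate images `l_med`, `l_o`, `l_u`, `l_b`, plus the
#'   threshold `p_r` actually used).
#' @export
extract_roi <- function(img, config = default_config()) {
  config <- validate_config(config)
  up <- upsample_nearest(img, config$upsample_to)
  l_med <- median_filter(up, config$median_mask)
  l_o <- switch(config$difference_polarity,
    opening_abs = morphological_open(l_med, config$se_radius_px),
    closing_abs = morphological_close(l_med, config$se_radius_px))
  l_u <- difference_image(l_o, l_med)
  mag <- abs(l_u)
  p_r <- config$binarization_threshold_pr
  if (is.na(p_r)) p_r <- auto_threshold_pr(mag, config)
  l_b <- binarize(mag, p_r)
  bridged <- binary_close(l_b, config$roi_bridge_px)
  roi <- largest_component_roi(bridged, config$connectivity)
  if (config$roi_fill_holes) {
    filled <- EBImage::fillHull(roi$mask * 1L) > 0L
    roi <- roi_mask_new(filled)
  }
  stack <- list(l_med = l_med, l_o = l_o, l_u = l_u, l_b = l_b, p_r = p_r)
  stopifnot(identical(dim(l_u), dim(l_med)))
  list(roi = roi, stack = stack)
}
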