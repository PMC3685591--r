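# Shared raster geometry.  Pixel (m, n) = (row, col), 1-based; a pixel
# belongs to a shape iff its integer center lies inside the shape
# boundary.  Rotations are expressed in the image plane: for an angle
# theta (degrees) the in-shape coordinates of a pixel offset
# (dr, dc) from the shape center are
#   u = cos(theta) * dc + sin(theta) * dr
#   v = -sin(theta) * dc + cos(theta) * dr
# Because a square grid is 90-degree symmetric, angles are meaningful
# modulo 90.

rotate_offsets <- function(dr, dc, angle_deg) {
  co <- cospi(angle_deg / 180)
  si <- sinpi(angle_deg / 180)
  list(u = co * dc + si * dr, v = -si * dc + co * dr)
}

# Filled rotated rectangle with half-sides (half_r, half_c) along its
# own (v, u) axes.  Half-open on the max edges so that abutting
# rectangles rasterise without double-counting shared boundary pixels.
rasterize_rect <- function(center, half_r, half_c, angle_deg, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  rad <- ceiling(sqrt(half_r^2 + half_c^2)) + 1L
  r0 <- max(1L, floor(center[1] - rad)); r1 <- min(shape[1], ceiling(center[1] + rad))
  c0 <- max(1L, floor(center[2] - rad)); c1 <- min(shape[2], ceiling(center[2] + rad))
  if (r0 > r1 || c0 > c1) return(out)
  rr <- r0:r1; cc <- c0:c1
  dr <- matrix(rr - center[1], length(rr), length(cc))
  dc <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  rc <- rotate_offsets(dr, dc, angle_deg)
  inside <- rc$u >= -half_c & rc$u < half_c & rc$v >= -half_r & rc$v < half_r
  out[rr, cc] <- inside
  out
}

#' Rasterize a rotated square pulse footprint
#'
#' A pixel belongs to the square iff its center lies inside the rotated
#' square boundary, half-open on the max edges (so abutting squares
#' tile without overlap).
#'
#' @param center `(row, col)` center in pixels.
#' @param side_px side length in pixels.
#' @param angle_deg rotation angle in degrees.
#' @param shape output `(rows, cols)`.
#' @return A logical matrix of the given shape.
#' @export
rasterize_square <- function(center, side_px, angle_deg, shape) {
  rasterize_rect(center, side_px / 2, side_px / 2, angle_deg, shape)
}

# Analytic rendering of a rectangle convolved with an isotropic
# Gaussian of sd sigma: separable product of normal-CDF differences in
# the rectangle's own frame.  sigma = 0 degenerates to the indicator.
blurred_rect_field <- function(center, half_r, half_c, angle_deg, sigma, shape,
                               support_sigmas = 5) {
  if (sigma <= 0) {
    return(rasterize_rect(center, half_r, half_c, angle_deg, shape) * 1.0)
  }
  out <- matrix(0, shape[1], shape[2])
  rad <- ceiling(sqrt(half_r^2 + half_c^2) + support_sigmas * sigma) + 1L
  r0 <- max(1L, floor(center[1] - rad)); r1 <- min(shape[1], ceiling(center[1] + rad))
  c0 <- max(1L, floor(center[2] - rad)); c1 <- min(shape[2], ceiling(center[2] + rad))
  if (r0 > r1 || c0 > c1) return(out)
  rr <- r0:r1; cc <- c0:c1
  dr <- matrix(rr - center[1], length(rr), length(cc))
  dc <- matrix(cc - center[2], length(rr), length(cc), byrow = TRUE)
  rc <- rotate_offsets(dr, dc, angle_deg)
  fu <- stats::pnorm((rc$u + half_c) / sigma) - stats::pnorm((rc$u - half_c) / sigma)
  fv <- stats::pnorm((rc$v + half_r) / sigma) - stats::pnorm((rc$v - half_r) / sigma)
  out[rr, cc] <- fu * fv
  out
}

# Even-odd point-in-polygon test for all pixel centers of a raster.
# poly: matrix with columns (row, col).
rasterize_polygon <- function(poly, shape) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > rr) != (yj > rr)) &
      (cc < (xj - xi) * (rr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# separable Gaussian blur with replicated edges (pure R, shift-accumulate)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (d in -r:r) {
    idx <- pmin(pmax(seq_len(nr) + d, 1L), nr)
    out <- out + k[d + r + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- matrix(0, nr, nc)
  for (d in -r:r) {
    idx <- pmin(pmax(seq_len(nc) + d, 1L), nc)
    m2 <- m2 + k[d + r + 1L] * out[, idx, drop = FALSE]
  }
  m2
}
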