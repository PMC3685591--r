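# Stage-two operators: edges, Radon angle estimation, derotation,
# detrending, watershed, square fitting.

make_roi <- function(mask) thermocov:::roi_mask_new(mask)

test_that("constant images yield no edges; a bright square yields its contour", {
  full <- make_roi(matrix(TRUE, 60, 60))
  expect_warning(e0 <- canny_edges(matrix(33, 60, 60), full), "no edges")
  expect_false(any(e0))
  m <- matrix(33, 80, 80)
  m[26:55, 26:55] <- 35.5          # 30 px axis-aligned square
  e <- canny_edges(m, make_roi(m > 34))
  len <- sum(e)
  expect_gt(len, 4 * 30 * 0.8)
  expect_lt(len, 4 * 30 * 1.6)
  # edges hug the square boundary
  idx <- which(e, arr.ind = TRUE)
  expect_true(all(idx >= 22 & idx <= 59))
})

test_that("lowering the high threshold never removes edges", {
  res <- std_analysis()
  roi <- res$rep$roi
  e_hi <- canny_edges(res$rep$stack$l_med, roi, low = 0.4, high = 0.9)
  e_lo <- canny_edges(res$rep$stack$l_med, roi, low = 0.4, high = 0.7)
  expect_true(all(which(e_hi) %in% which(e_lo)))
})

test_that("radon projections conserve edge mass at every angle", {
  set.seed(10)
  edges <- matrix(runif(80 * 80) > 0.97, 80, 80)
  sino <- radon_transform(edges, 1)
  expect_true(all(colSums(sino$values) == sum(edges)))
  # single point: unit mass at every angle
  pt <- matrix(FALSE, 40, 40); pt[17, 23] <- TRUE
  sp <- radon_transform(pt, 0.5)
  expect_true(all(colSums(sp$values) == 1))
  expect_true(all(apply(sp$values, 2, max) == 1))
  expect_error(radon_transform(matrix(FALSE, 10, 10)), "no edges")
})

test_that("a line of pixels concentrates into one bin at its own angle", {
  # line along the row axis (constant column): peak bin of ~50 at 0 degrees
  e <- matrix(FALSE, 120, 120); e[31:80, 60] <- TRUE
  sino <- radon_transform(e, 1)
  scores <- apply(sino$values, 2, max)
  expect_equal(sino$angles_deg[which.max(scores)], 0)
  expect_equal(max(scores), 50)
  expect_equal(as.numeric(estimate_grid_angle(sino)), 0)
  # the same line rotated by 30 degrees peaks 30 degrees away
  shape <- c(120L, 120L)
  rot <- matrix(FALSE, 120, 120)
  t_seq <- seq(-25, 25, by = 0.25)
  rr <- round(60 + t_seq * cospi(30 / 180))
  cc <- round(60 - t_seq * sinpi(30 / 180))
  rot[cbind(rr, cc)] <- TRUE
  sino30 <- radon_transform(rot, 1)
  est30 <- as.numeric(estimate_grid_angle(sino30))
  expect_lte(min(abs(est30 - 30) %% 90, 90 - abs(est30 - 30) %% 90), 1)
})

test_that("grid angle is recovered modulo 90 with smallest-angle ties", {
  res <- std_analysis()     # grid at 17 degrees
  edges <- canny_edges(res$rep$stack$l_med, res$rep$roi)
  sino <- radon_transform(edges, 0.5)
  est <- as.numeric(estimate_grid_angle(sino))
  expect_lte(abs(est - 17), 1)
  # axis-aligned grid
  gen0 <- generate_scene(scene_small(angle_deg = 0))
  rep0 <- analyze_image(gen0$image, small_config())
  expect_lte(min(rep0$angle_deg, 90 - rep0$angle_deg), 1)
  # a grid rotated by 107 degrees is a 17-degree grid modulo the
  # square's symmetry
  gen107 <- generate_scene(scene_small(angle_deg = 107))
  rep107 <- analyze_image(gen107$image, small_config())
  expect_lte(abs(rep107$angle_deg - 17), 1)
})

test_that("derotation is the identity at 0 and invertible within tolerance", {
  set.seed(11)
  m <- matrix(rnorm(50 * 50), 50, 50)
  expect_identical(derotate(m, 0), m)
  mask <- rasterize_square(c(25, 25), 24, 31, c(50L, 50L))
  for (a in c(10, 31, 44)) {
    back <- derotate(derotate(mask, a), -a)
    inter <- sum(back & mask); uni <- sum(back | mask)
    expect_gte(inter / uni, 0.95)
    expect_lte(abs(sum(derotate(mask, a)) - sum(mask)) / sum(mask), 0.05)
  }
  expect_true(is.logical(derotate(mask, 33)))
})

test_that("constant-component removal centers the region and ignores offsets", {
  res <- std_analysis()
  roi <- res$rep$roi
  m <- res$rep$stack$l_med
  det <- remove_constant_component(m, roi)
  expect_lt(abs(mean(det[roi$mask])), 1e-9)
  expect_true(all(det[!roi$mask] == 0))
  det_off <- remove_constant_component(m + 5, roi)
  expect_equal(det_off, det)
  # local background removal is offset-invariant too
  det_loc <- remove_constant_component(m, roi, method = "local")
  det_loc_off <- remove_constant_component(m + 5, roi, method = "local")
  expect_equal(det_loc_off, det_loc)
  # relative peak heights survive detrending
  pk <- vapply(res$rep$pulses, function(p)
    det[round(p$center[1]), round(p$center[2])], numeric(1))
  expect_lt(diff(range(pk)) / mean(pk - min(det[roi$mask])), 0.25)
})

test_that("watershed separates plateaus and partitions the region", {
  x <- matrix(0, 40, 80)
  x[11:30, 11:30] <- 2.5
  x[11:30, 51:70] <- 2.5
  roi <- make_roi(x > 0)
  labs <- watershed_pulses(x, roi, h = 0.3)
  expect_equal(max(labs), 2L)
  expect_true(all((labs > 0) == roi$mask))
  res <- std_analysis()
  det <- remove_constant_component(res$rep$stack$l_med, res$rep$roi)
  labs2 <- watershed_pulses(det, res$rep$roi)
  expect_true(abs(max(labs2) - 12) <= 1)
  expect_true(all((labs2 > 0) == res$rep$roi$mask))
  expect_error(watershed_pulses(matrix(0, 20, 20),
                                make_roi(matrix(FALSE, 20, 20))),
               "empty region")
})

test_that("square fitting recovers plateaus and discards specks", {
  # single perfect 20x20 plateau
  shape <- c(60L, 60L)
  det <- matrix(0, shape[1], shape[2])
  det[21:40, 16:35] <- 1
  labs <- matrix(0L, shape[1], shape[2]); labs[det > 0] <- 1L
  p <- fit_squares(labs, det, 0, default_config())
  expect_length(p, 1)
  expect_lte(abs(p[[1]]$side_px - 20), 1)
  expect_lte(max(abs(p[[1]]$center - c(30.5, 25.5))), 1)
  # twelve equal squares plus a 3-px speck: speck discarded
  res <- std_analysis()
  det2 <- remove_constant_component(res$rep$stack$l_med, res$rep$roi)
  labs2 <- watershed_pulses(det2, res$rep$roi)
  speck_labs <- labs2
  free <- which(labs2 == 0L)[1:3]
  speck_labs[free] <- max(labs2) + 1L
  p2 <- fit_squares(speck_labs, det2, res$rep$angle_deg, analysis_config())
  expect_length(p2, max(labs2))
  expect_equal(attr(p2, "discarded"), max(labs2) + 1L)
  expect_error(fit_squares(matrix(0L, 5, 5), matrix(0, 5, 5), 0), "no valid")
})

test_that("fitted centers match the generated grid to sub-pixel accuracy", {
  res <- std_analysis()
  tr <- as.matrix(scene_standard()$pulses[, c("center_row", "center_col")])
  est <- t(vapply(res$rep$pulses, function(p) p$center, numeric(2)))
  errs <- vapply(seq_len(nrow(est)), function(i)
    min(sqrt(rowSums((tr - matrix(est[i, ], nrow(tr), 2, byrow = TRUE))^2))),
    numeric(1))
  expect_lte(mean(errs), 2)
  expect_lte(max(errs), 3)
})

test_that("pulse masks are consistent with their center, side and angle", {
  res <- std_analysis()
  for (p in res$rep$pulses[c(1, 6, 12)]) {
    expect_identical(p$mask,
                     rasterize_square(p$center, p$side_px, p$angle_deg,
                                      dim(res$rep$roi$mask)))
    expect_equal(sum(p$mask), p$side_px^2, tolerance = 0.1)
  }
})
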