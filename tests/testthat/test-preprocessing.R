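# Stage-one operators: upsampling, filters, binarization, labelling,
# and the composed region-of-interest extraction.

test_that("nearest-neighbour upsampling replicates values exactly", {
  m <- matrix(c(1, 3, 2, 4) + 33, 2, 2)
  up <- upsample_nearest(thermal_image(matrix(33, 8, 8)), c(8, 8))
  expect_identical(dim(up), c(8L, 8L))
  # 2x2 -> 4x4 block replication, checked against the direct block map
  m4 <- thermocov:::img_values(
    upsample_nearest(structure(m, class = "matrix"), c(4, 4)))
  expect_identical(m4, m[c(1, 1, 2, 2), c(1, 1, 2, 2)])
  # camera frame to working resolution; no interpolated values appear
  set.seed(5)
  cam <- matrix(runif(320 * 256, 30, 36), 320, 256)
  big <- upsample_nearest(thermal_image(cam), c(480, 640))
  expect_identical(dim(big), c(480L, 640L))
  expect_true(all(thermocov:::img_values(big) %in% cam))
  expect_error(upsample_nearest(thermal_image(cam), c(200, 640)),
               "at least the source size")
})

test_that("median filter matches a brute-force sort-and-pick oracle", {
  expect_identical(median_filter(matrix(7.5, 6, 6)), matrix(7.5, 6, 6))
  # single hot pixel is rejected
  m <- matrix(33, 9, 9); m[5, 5] <- 43
  expect_true(all(median_filter(m) == 33))
  # arbitrary 5x5 image against an exhaustive per-pixel oracle
  set.seed(6)
  x <- matrix(rnorm(25), 5, 5)
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), 5); jj <- min(max(j + dj, 1), 5)
      vals <- c(vals, x[ii, jj])
    }
    oracle[i, j] <- sort(vals)[5]
  }
  expect_equal(median_filter(x), oracle)
  expect_error(median_filter(x, c(2, 3)), "odd")
})

test_that("grayscale opening is anti-extensive, idempotent and matches brute force", {
  expect_identical(morphological_open(matrix(2, 9, 9), 2), matrix(2, 9, 9))
  set.seed(7)
  x <- matrix(rnorm(81), 9, 9)
  op <- morphological_open(x, 1)
  expect_true(all(op <= x + 1e-12))
  expect_equal(morphological_open(op, 1), op)
  # brute-force erosion-then-dilation oracle with clipped 3x3 windows
  win <- function(m, i, j, f) {
    v <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m))
        v <- c(v, m[ii, jj])
    }
    f(v)
  }
  er <- matrix(NA_real_, 9, 9); di <- matrix(NA_real_, 9, 9)
  for (i in 1:9) for (j in 1:9) er[i, j] <- win(x, i, j, min)
  for (i in 1:9) for (j in 1:9) di[i, j] <- win(er, i, j, max)
  expect_equal(op, di)
  # plateau wider than the element survives, narrow peak is flattened
  p <- matrix(0, 15, 15)
  p[4:12, 4:12] <- 1     # 9x9 plateau vs 3x3 element
  p[2, 2] <- 5           # isolated peak
  po <- morphological_open(p, 1)
  expect_equal(po[8, 8], 1)
  expect_equal(po[2, 2], 0)
  expect_error(morphological_open(matrix(0, 4, 4), 2), "larger than the image")
})

test_that("difference image is exact elementwise subtraction", {
  a <- matrix(rnorm(20), 4, 5)
  expect_true(all(difference_image(a, a) == 0))
  expect_true(all(abs(difference_image(a + 2, a) - 2) < 1e-12))
  b <- matrix(rnorm(20), 4, 5)
  oracle <- matrix(NA_real_, 4, 5)
  for (i in 1:4) for (j in 1:5) oracle[i, j] <- a[i, j] - b[i, j]
  expect_identical(difference_image(a, b), oracle)
  expect_error(difference_image(a, matrix(0, 5, 4)), "shape mismatch")
})

test_that("binarization is a strict threshold", {
  m <- matrix(seq(0, 3, length.out = 12), 3, 4)
  expect_false(any(binarize(m, 3.5)))
  expect_true(all(binarize(m, -1)))
  expect_identical(binarize(m, 1.0), m > 1.0)
  expect_error(binarize(m, NA), "finite")
})

test_that("binarized area tracks the ground-truth union for hard footprints", {
  sc <- scene_grid(angle_deg = 13, noise_sd_c = 0, seed = 9,
                   beam_sigma_px = 0, mound_amp_c = 0)
  gen <- generate_scene(sc)
  pre <- extract_roi(gen$image, default_config(binarization_threshold_pr = 1.0))
  n_true <- sum(gen$truth$union_mask)
  expect_lt(abs(sum(pre$stack$l_b) - n_true) / n_true, 0.02)
})

test_that("largest component selection agrees with a flood-fill oracle", {
  m <- matrix(FALSE, 20, 20)
  m[2:6, 2:11] <- TRUE    # 50 px
  m[15:16, 15:19] <- TRUE # 10 px
  roi <- largest_component_roi(m)
  expect_equal(roi$n_pixels, 50L)
  expect_true(all(roi$mask[2:6, 2:11]))
  # single component: identity
  one <- matrix(FALSE, 10, 10); one[3:5, 4:8] <- TRUE
  expect_identical(largest_component_roi(one)$mask, one)
  expect_error(largest_component_roi(matrix(FALSE, 5, 5)), "no treated region")
  # random blobs vs an independent flood-fill component-size oracle
  flood_sizes <- function(mask, conn8 = TRUE) {
    seen <- matrix(FALSE, nrow(mask), ncol(mask))
    sizes <- integer(0)
    nb <- if (conn8) expand.grid(di = -1:1, dj = -1:1)[-5, ] else
      data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
    for (start in which(mask)) {
      if (seen[start]) next
      stack <- start; n <- 0L
      while (length(stack)) {
        p <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (seen[p] || !mask[p]) next
        seen[p] <- TRUE; n <- n + 1L
        pi <- (p - 1L) %% nrow(mask) + 1L; pj <- (p - 1L) %/% nrow(mask) + 1L
        for (k in seq_len(nrow(nb))) {
          ii <- pi + nb$di[k]; jj <- pj + nb$dj[k]
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] && !seen[ii, jj])
            stack <- c(stack, (jj - 1L) * nrow(mask) + ii)
        }
      }
      sizes <- c(sizes, n)
    }
    sizes
  }
  set.seed(8)
  for (trial in 1:5) {
    blob <- matrix(runif(30 * 30) > 0.72, 30, 30)
    if (!any(blob)) next
    expect_equal(largest_component_roi(blob)$n_pixels,
                 max(flood_sizes(blob)))
  }
})

test_that("region extraction recovers the treated field and excludes artifacts", {
  res <- std_analysis()
  ratio <- res$rep$roi$n_pixels / sum(res$gen$truth$roi_mask)
  expect_gte(ratio, 0.95)
  expect_lte(ratio, 1.10)
  # blank scene: nothing to detect
  blank <- thermal_image(matrix(33, 480, 640))
  expect_error(extract_roi(blank, default_config()), "no treated region")
  # an isolated hot artifact far from the grid stays out of the region
  img <- thermocov:::img_values(res$gen$image)
  img[20:24, 20:24] <- img[20:24, 20:24] + 2.5
  pre2 <- extract_roi(thermal_image(img), analysis_config())
  expect_false(any(pre2$roi$mask[1:40, 1:40]))
  expect_lte(abs(pre2$roi$n_pixels - res$rep$roi$n_pixels), 10)
})

test_that("pipeline is deterministic for identical input and config", {
  gen <- generate_scene(scene_small(noise_sd_c = 0.05))
  a <- extract_roi(gen$image, small_config())
  b <- extract_roi(gen$image, small_config())
  expect_identical(a$roi$mask, b$roi$mask)
  expect_identical(a$stack, b$stack)
})
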