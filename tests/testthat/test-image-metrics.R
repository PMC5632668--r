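small_geom <- function(w, h) image_geometry(w, h, deg_per_px = 0.1)

test_that("gaussian window matches direct evaluation, including far offsets", {
  w <- gaussian_window(window_spec(1, 3))
  expect_equal(dim(w), c(7, 7))
  expect_identical(w[4, 4], 1)
  expect_equal(w[4, 5], exp(-0.5))
  expect_equal(w[3, 3], exp(-1))

  # large-sigma limit: weights near the center tend to uniform
  wu <- gaussian_window(window_spec(200))
  ctr <- 601
  expect_true(all(abs(wu[ctr + (-10:10), ctr + (-10:10)] - 1) < 1e-2))

  # scalar oracle at the experiment's sigma
  sp <- window_spec(19.4, 59)
  wb <- gaussian_window(sp)
  expect_equal(wb[60, 60 + 27], exp(-(27^2) / (2 * 19.4^2)), tolerance = 1e-12)

  expect_error(window_spec(-1), "positive")
  expect_error(window_spec(2, 3), "truncation")
})

test_that("contrast energy map obeys the zero and scale-invariance laws", {
  img <- luminance_image(matrix(100, 12, 12), small_geom(12, 12))
  m <- contrast_energy_map(img, window_spec(1.5))
  expect_true(all(m$values == 0))
  expect_equal(m$n_undefined, 0)

  set.seed(3)
  X <- matrix(exp(rnorm(100)), 10, 10)
  g <- small_geom(10, 10)
  sp <- window_spec(1.2)
  m1 <- contrast_energy_map(luminance_image(X, g), sp)$values
  for (c in c(0.25, 7, 1234)) {
    mc <- contrast_energy_map(luminance_image(c * X, g), sp)$values
    expect_equal(mc, m1, tolerance = 1e-10)
  }
})

test_that("vectorized map equals the literal double-sum oracle", {
  sp1 <- window_spec(1, 3)
  # 5x5 single bright pixel
  X <- matrix(100, 5, 5); X[3, 3] <- 500
  got <- contrast_energy_map(luminance_image(X, small_geom(5, 5)), sp1)$values
  expect_equal(got, bf_contrast_energy(X, 1, 3), tolerance = 1e-10)

  # random 8x8 fixtures, both variants, border renormalization included
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(runif(64, 10, 200), 8, 8)
    img <- luminance_image(X, small_geom(8, 8))
    for (variant in c("rms", "squared")) {
      got <- contrast_energy_map(img, sp1, variant)$values
      expect_equal(got, bf_contrast_energy(X, 1, 3, variant),
                   tolerance = 1e-10)
    }
  }
})

test_that("all-zero windows are flagged as undefined, not zeroed", {
  X <- matrix(100, 12, 12)
  X[1:9, 1:9] <- 0
  m <- contrast_energy_map(luminance_image(X, small_geom(12, 12)),
                           window_spec(0.8, 3))
  expect_gt(m$n_undefined, 0)
  expect_true(anyNA(m$values))
  # a region over the undefined zone propagates an error, never a silent 0
  mask <- matrix(FALSE, 12, 12); mask[3:5, 3:5] <- TRUE
  expect_error(
    contrast_energy_change(luminance_image(X, small_geom(12, 12)),
                           luminance_image(X + 1, small_geom(12, 12)),
                           change_region(mask), window_spec(0.8, 3)),
    "undefined")
})

test_that("contrast energy change: identity, symmetry, oracle, crop", {
  set.seed(11)
  X <- matrix(runif(256, 50, 150), 16, 16)
  g <- small_geom(16, 16)
  mask <- matrix(FALSE, 16, 16); mask[5:9, 6:10] <- TRUE
  region <- change_region(mask)
  sp <- window_spec(1, 3)

  orig <- luminance_image(X, g)
  expect_equal(contrast_energy_change(orig, orig, region, sp), 0)

  # scale the region's deviations x2
  Y <- X; m <- mean(X[mask]); Y[mask] <- m + 2 * (X[mask] - m)
  manip <- luminance_image(Y, g)
  got <- contrast_energy_change(orig, manip, region, sp)
  bo <- bf_contrast_energy(X, 1, 3); bm <- bf_contrast_energy(Y, 1, 3)
  expect_equal(got, abs(mean(bo[mask]) - mean(bm[mask])), tolerance = 1e-10)
  expect_gt(got, 0)

  # symmetry and crop-equivalence
  expect_equal(contrast_energy_change(manip, orig, region, sp), got)
  expect_equal(contrast_energy_change(orig, manip, region, sp, crop = FALSE),
               got, tolerance = 1e-12)

  g2 <- small_geom(8, 8)
  expect_error(contrast_energy_change(
    orig, luminance_image(X[1:8, 1:8], g2), region, sp), "mismatch")
})

test_that("subjective importance change sums region values and is additive", {
  mk_mask <- function(rows, cols) {
    m <- matrix(FALSE, 10, 10); m[rows, cols] <- TRUE; m
  }
  ones <- importance_map(matrix(1, 10, 10))
  expect_equal(subjective_importance_change(ones, change_region(mk_mask(1:5, 1:10))), 50)
  expect_equal(subjective_importance_change(importance_map(matrix(0, 10, 10)),
                                            change_region(mk_mask(1:5, 1:10))), 0)
  expect_equal(subjective_importance_change(importance_map(matrix(0.4, 10, 10)),
                                            change_region(mk_mask(1:5, 1:5))), 10)

  # additivity over a random partition
  set.seed(5)
  iv <- importance_map(matrix(round(runif(100) * 5) / 5, 10, 10))
  full <- mk_mask(2:9, 2:9)
  split_mask <- matrix(sample(c(TRUE, FALSE), 100, replace = TRUE), 10, 10)
  a <- full & split_mask; b <- full & !split_mask
  if (any(a) && any(b)) {
    expect_equal(subjective_importance_change(iv, change_region(full)),
                 subjective_importance_change(iv, change_region(a)) +
                   subjective_importance_change(iv, change_region(b)))
  }
})

test_that("diff_region recovers the altered pixels", {
  g <- small_geom(20, 20)
  X <- matrix(100, 20, 20)
  orig <- luminance_image(X, g)
  Y <- X; Y[7, 13] <- 150
  r1 <- diff_region(orig, luminance_image(Y, g))
  expect_equal(r1$n_px, 1L)
  expect_equal(unname(r1$centroid_px), c(12, 6))  # 0-based (x, y)

  expect_error(diff_region(orig, orig), class = "changescope_no_change")

  Z <- X; Z[4:13, 6:15] <- X[4:13, 6:15] + 20
  r2 <- diff_region(orig, luminance_image(Z, g), tol = 0)
  expect_equal(r2$n_px, 100L)
  want <- matrix(FALSE, 20, 20); want[4:13, 6:15] <- TRUE
  expect_identical(r2$mask, want)
})

test_that("region covariates: eccentricity, luminance, spatial frequency", {
  geom <- default_geometry()
  set.seed(8)
  X <- matrix(runif(geom$height_px * geom$width_px, 50, 150),
              geom$height_px, geom$width_px)
  img <- luminance_image(X, geom)
  sp <- window_spec(2, 6)

  # single pixel at the exact image center: eccentricity 0
  cmask <- matrix(FALSE, geom$height_px, geom$width_px)
  cmask[161, 241] <- TRUE  # 0-based (240, 160) = center of 481 x 321
  cv <- region_covariates(img, luminance_image(X + cmask * 10, geom),
                          change_region(cmask), sp)
  expect_equal(cv$eccentricity_deg, 0)
  expect_equal(cv$size_px, 1L)

  # a centroid 41.4 px out converts to (just under) the 1.6 deg boundary
  expect_equal(pixels_to_degrees(41.4, geom), 1.6, tolerance = 1e-2)

  # orig == manip on the region: zero luminance and sf change
  mask <- matrix(FALSE, geom$height_px, geom$width_px)
  mask[40:59, 60:79] <- TRUE
  cv2 <- region_covariates(img, img, change_region(mask), sp)
  expect_equal(cv2$luminance_change, 0)
  expect_equal(cv2$sf_change, 0)
  expect_equal(cv2$ce_change, 0)
  expect_equal(cv2$size_px, 400L)
  expect_gte(cv2$min_contrast, 0)
  expect_gte(cv2$max_contrast, cv2$mean_contrast)
})

test_that("pixel/degree conversion reproduces the experiment's geometry", {
  g <- default_geometry()
  expect_equal(pixels_to_degrees(19.4, g), 0.75, tolerance = 1e-2)
  expect_equal(pixels_to_degrees(0, g), 0)
  expect_equal(pixels_to_degrees(481, g), 18.6)
  expect_equal(degrees_to_pixels(pixels_to_degrees(123.4, g), g), 123.4)
})
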