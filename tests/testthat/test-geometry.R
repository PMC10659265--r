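test_that("soma_center is the 7-electrode weighted centroid", {
  arr <- hex_array(2, 30)
  ctr <- which(rowSums(arr$positions^2) < 1e-9)
  nb_east <- which(abs(arr$positions[, 1] - 30) < 1e-9 &
                     abs(arr$positions[, 2]) < 1e-9)
  A <- matrix(0, 3, arr$n)

  # all weight on one electrode -> that electrode's position
  A[1, nb_east] <- 5
  expect_equal(soma_center(A, arr), arr$positions[nb_east, ])

  # equal weights on argmax + 6 hex neighbors -> the center position
  A2 <- matrix(0, 3, arr$n)
  A2[1, ctr] <- 1 + 1e-9
  A2[1, neighbor_indices(arr, ctr, 6L)] <- 1
  expect_equal(soma_center(A2, arr), c(0, 0), tolerance = 1e-9)

  # weights 2 at (0,0) and 1 at (30,0) -> (10, 0)
  A3 <- matrix(0, 3, arr$n)
  A3[1, ctr] <- 2; A3[1, nb_east] <- 1
  expect_equal(soma_center(A3, arr), c(10, 0), tolerance = 1e-12)

  expect_error(soma_center(matrix(0, 3, arr$n), arr), "somatic")
})

test_that("dendritic_center thresholds and averages correctly", {
  arr <- hex_array(2, 30)
  A <- matrix(0, 3, arr$n)
  # single suprathreshold electrode
  A[2, 5] <- 1
  expect_equal(dendritic_center(A, arr), arr$positions[5, ])
  # symmetric ring of equal amplitudes -> ring center
  ring <- which(abs(sqrt(rowSums(arr$positions^2)) - 30) < 1e-6)
  A2 <- matrix(0, 3, arr$n); A2[2, ring] <- 1
  expect_equal(dendritic_center(A2, arr), c(0, 0), tolerance = 1e-9)
  # sub-threshold electrodes are excluded
  A3 <- A2; A3[2, which.max(arr$positions[, 1])] <- 0.05
  expect_equal(dendritic_center(A3, arr, threshold_frac = 0.1), c(0, 0),
               tolerance = 1e-9)
  expect_error(dendritic_center(matrix(0, 3, arr$n), arr), "dendritic")
})

test_that("centers are equivariant under rotation and translation", {
  set.seed(12)
  arr <- hex_array(2, 30)
  A <- matrix(runif(3 * arr$n), 3, arr$n)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  shift <- c(120, -45)
  arr2 <- electrode_array(t(R %*% t(arr$positions)) +
                            rep(shift, each = arr$n), 30, recenter = FALSE)
  expect_equal(soma_center(A, arr2),
               drop(R %*% soma_center(A, arr)) + shift, tolerance = 1e-9)
  expect_equal(dendritic_center(A, arr2),
               drop(R %*% dendritic_center(A, arr)) + shift, tolerance = 1e-9)
})

test_that("ransac_affine recovers exact and outlier-contaminated maps", {
  set.seed(13)
  L <- matrix(c(1.2, 0.3, -0.1, 0.8), 2, 2); off <- c(5, -2)
  src <- matrix(runif(100, 0, 400), 50, 2)
  dst <- t(L %*% t(src) + off)

  tf <- ransac_affine(src, dst, inlier_tol = 1e-6, seed = 1)
  expect_equal(tf$linear, L, tolerance = 1e-9)
  expect_equal(tf$offset, off, tolerance = 1e-9)

  # identity correspondences
  tfi <- ransac_affine(src, src, inlier_tol = 1e-6, seed = 1)
  expect_equal(tfi$linear, diag(2), tolerance = 1e-9)
  expect_equal(tfi$offset, c(0, 0), tolerance = 1e-8)

  # 30% gross outliers
  dst2 <- dst
  out <- sample(50, 15)
  dst2[out, ] <- dst2[out, ] + matrix(runif(30, 200, 600), 15, 2)
  tf2 <- ransac_affine(src, dst2, inlier_tol = 1e-3, seed = 2)
  expect_equal(tf2$linear, L, tolerance = 1e-6)
  expect_identical(sort(which(!tf2$inlier_mask)), sort(out))

  # 0% outliers: equals plain least squares with noise
  dst3 <- dst + matrix(rnorm(100, 0, 0.5), 50, 2)
  tf3 <- ransac_affine(src, dst3, inlier_tol = 10, seed = 3)
  tf_ls <- eidecomp:::ls_affine(src, dst3)
  expect_equal(tf3$linear, tf_ls$linear, tolerance = 1e-12)

  # transform inversion round-trips
  inv <- invert_affine(tf)
  expect_equal(apply_affine(inv, apply_affine(tf, src)), src,
               tolerance = 1e-9)

  col <- cbind(1:10, 2 * (1:10))
  expect_error(ransac_affine(col, col, seed = 1), "collinear")
})

test_that("sta_rf_center recovers centers to sub-pixel accuracy", {
  arr <- hex_array(2, 30)
  cell <- synthesize_cell(arr, "ON_parasol", rf_center_xy = c(13.4, 24.7),
                          rf_sigma = 2.5, seed = 6)
  # noiseless STA
  sta <- synthesize_sta(cell, nx = 40L, ny = 40L, noise_sd = 0)
  est <- sta_rf_center(sta)
  expect_lt(sqrt(sum((est$center_xy - c(13.4, 24.7))^2)), 0.5)
  expect_gt(est$diameter, 0)

  # with realistic noise
  stan <- synthesize_sta(cell, nx = 40L, ny = 40L, noise_sd = 0.05, seed = 2)
  estn <- sta_rf_center(stan)
  expect_lt(sqrt(sum((estn$center_xy - c(13.4, 24.7))^2)), 1)

  # OFF polarity leaves the center unchanged
  esto <- sta_rf_center(-sta)
  expect_equal(esto$center_xy, est$center_xy, tolerance = 1e-9)

  # single hot pixel
  sta1 <- array(0, c(20, 20, 10))
  sta1[7, 12, ] <- c(0, 0, 0.1, 0.5, 1, 0.4, 0, 0, 0, 0)
  sta1 <- sta1 + array(rnorm(4000, 0, 1e-3), c(20, 20, 10))
  est1 <- sta_rf_center(sta1, significance_z = 10)
  expect_equal(est1$center_xy, c(6.5, 11.5), tolerance = 0.05)

  expect_error(sta_rf_center(array(rnorm(4000), c(20, 20, 10)),
                             significance_z = 50), "significant")
})

test_that("rf_prediction_fit is exact on affine ground truth and nested", {
  set.seed(14)
  n <- 20
  soma <- matrix(runif(2 * n, -200, 200), n, 2)
  dend <- soma + matrix(rnorm(2 * n, 0, 40), n, 2)
  L <- matrix(c(0.02, 0.003, -0.002, 0.021), 2, 2)

  # rf is an exact affine image of the somas -> soma-only error 0
  rf1 <- t(L %*% t(soma) + c(3, 4))
  f1 <- rf_prediction_fit(soma, dend, rf = rf1, diameters = 4,
                          mode = "soma_only")
  expect_lt(f1$median_error, 1e-10)

  # rf depends on the dendritic centers -> dendrites eliminate the error
  rf2 <- t(L %*% t(0.5 * (soma + dend)) + c(3, 4))
  f2s <- rf_prediction_fit(soma, dend, rf = rf2, diameters = 4,
                           mode = "soma_only")
  f2d <- rf_prediction_fit(soma, dend, rf = rf2, diameters = 4,
                           mode = "soma_plus_dendrite")
  expect_lt(f2d$median_error, 1e-10)
  expect_gt(f2s$median_error, 0.01)

  # nested least squares: richer predictors never increase in-sample error
  rf3 <- rf2 + matrix(rnorm(2 * n, 0, 2), n, 2)
  e_s <- rf_prediction_fit(soma, dend, rf = rf3, diameters = 4,
                           mode = "soma_only")$normalized_errors
  e_sd <- rf_prediction_fit(soma, dend, rf = rf3, diameters = 4,
                            mode = "soma_plus_dendrite")$normalized_errors
  expect_lte(sum(e_sd^2), sum(e_s^2) + 1e-9)

  expect_error(rf_prediction_fit(soma[1:3, ], rf = rf1[1:3, ], diameters = 4,
                                 mode = "soma_only"), "at least")
})
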