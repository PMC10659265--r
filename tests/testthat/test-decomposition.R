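test_that("per-electrode fit recovers constructed shifts and amplitudes", {
  B <- stereotyped_templates(T = 96L, pre = 32L)
  # zero trace -> zero amplitudes, zero objective
  r0 <- fit_shifts_amplitudes_electrode(rep(0, 96), B, lambda = 0.1)
  expect_equal(unname(r0$amplitudes), c(0, 0, 0))
  expect_equal(r0$objective, 0)

  # noiseless two-compartment superposition
  x <- 2.0 * circ_shift(B[1, ], 5) + 0.5 * circ_shift(B[3, ], 12)
  r <- fit_shifts_amplitudes_electrode(x, B, lambda = 1e-4)
  expect_equal(r$shifts[1], 5L)
  expect_equal(r$shifts[3], 12L)
  expect_equal(r$amplitudes[1], 2.0, tolerance = 1e-3)
  expect_equal(r$amplitudes[3], 0.5, tolerance = 1e-3)
  expect_lt(r$amplitudes[2], 1e-2)
})

test_that("the default search attains the exhaustive-search objective on toys", {
  set.seed(55)
  for (i in 1:10) {
    T <- 32L
    B <- stereotyped_templates(T = T, pre = 10L)
    x <- runif(1, 0.5, 2) * circ_shift(B[1, ], sample(0:31, 1)) +
      runif(1, 0, 1) * circ_shift(B[2, ], sample(0:31, 1)) +
      runif(1, 0, 1) * circ_shift(B[3, ], sample(0:31, 1)) + rnorm(T, 0, 0.05)
    r1 <- fit_shifts_amplitudes_electrode(x, B, 0.05, shift_search())
    r2 <- fit_shifts_amplitudes_electrode(x, B, 0.05, shift_search("exhaustive"))
    expect_lte(r1$objective, r2$objective + 1e-9 * abs(r2$objective))
  }
})

test_that("electrode subproblems are order-independent", {
  set.seed(41)
  gt <- tiny_recovery(T = 96L, noise_sd = 2)
  prior <- build_shape_prior(gt$cell$templates, lambda_l = 1, lambda_p = 1)
  f1 <- fit_amplitudes_shifts(gt$ei, gt$cell$templates, prior)
  perm <- sample(gt$arr$n)
  ei_p <- electrical_image(gt$ei$data[, perm],
                           electrode_array(gt$arr$positions[perm, ], 30,
                                           recenter = FALSE),
                           pre_samples = gt$ei$pre_samples)
  f2 <- fit_amplitudes_shifts(ei_p, gt$cell$templates, prior)
  expect_equal(f2$amplitudes, f1$amplitudes[, perm])
  expect_equal(f2$shifts, f1$shifts[, perm])
})

test_that("zero EI gives all-zero amplitudes", {
  arr <- hex_array(1, 30)
  ei <- electrical_image(matrix(0, 48, arr$n), arr, pre_samples = 16L)
  pr <- build_shape_prior(stereotyped_templates(T = 48L, pre = 16L),
                          lambda_l = 0.5, lambda_p = 1)
  f <- fit_amplitudes_shifts(ei, pr$mu, pr)
  expect_true(all(f$amplitudes == 0))
})

test_that("a zero basis row forces its amplitude to zero with a warning", {
  B <- stereotyped_templates(T = 48L, pre = 16L)
  B[2, ] <- 0
  x <- 1.5 * circ_shift(B[1, ], 3)
  expect_warning(r <- fit_shifts_amplitudes_electrode(x, B, 1e-3), "zero")
  expect_equal(r$amplitudes[2], 0)
  expect_equal(r$shifts[1], 3L)
})

test_that("decomposition objective terms and gradient are consistent", {
  set.seed(61)
  gt <- tiny_recovery(T = 48L)
  pr <- build_shape_prior(gt$cell$templates, lambda_l = 0.3, lambda_p = 2)
  A <- gt$cell$true_amplitudes
  tau <- gt$cell$true_shifts
  B <- gt$cell$templates

  # perfect fit with both weights zero -> 0
  pr0 <- build_shape_prior(B, lambda_l = 0, lambda_p = 0)
  expect_equal(decomposition_objective(gt$ei, B, A, tau, pr0), 0,
               tolerance = 1e-18 + 1e-9 * sum(gt$ei$data^2))

  # A = 0 -> half the squared data norm plus the prior term
  prm <- build_shape_prior(0 * B, lambda_l = 0.3, lambda_p = 2)
  obj0 <- decomposition_objective(gt$ei, B, 0 * A, tau, prm)
  expect_equal(obj0, 0.5 * sum(gt$ei$data^2) +
                 eidecomp:::prior_penalty(B, prm), tolerance = 1e-10)

  # finite-difference gradient in one amplitude
  eps <- 1e-5
  n <- which.max(A[1, ]); A1 <- A
  f <- function(a) { A1[1, n] <- a; decomposition_objective(gt$ei, B, A1, tau, pr) }
  num <- (f(A[1, n] + eps) - f(A[1, n] - eps)) / (2 * eps)
  recon <- eidecomp:::reconstruct_matrix(B, A, tau)
  resid <- recon[, n] - gt$ei$data[, n]
  ana <- sum(resid * circ_shift(B[1, ], tau[1, n])) +
    pr$lambda_l * A[1, n] / sqrt(sum(A[1:2, n]^2))
  expect_equal(num, ana, tolerance = 1e-5)
})

test_that("full decomposition drives noiseless reconstruction error to ~0", {
  gt <- tiny_recovery(T = 96L, noise_sd = 0)
  pr <- build_shape_prior(gt$cell$templates, gt$ei$sampling_rate,
                          lambda_l = 1e-3, lambda_p = 0.1)
  fit <- fit_decomposition(gt$ei, pr, max_iters = 20L)
  expect_lt(sum(residuals(fit)^2) / sum(gt$ei$data^2), 1e-4)
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-9 * abs(tr[1])))
})

test_that("pure-noise EIs are mostly zeroed under strong group sparsity", {
  set.seed(77)
  arr <- hex_array(2, 30)
  ei <- electrical_image(matrix(rnorm(96 * arr$n, 0, 1), 96), arr,
                         pre_samples = 32L)
  pr <- build_shape_prior(stereotyped_templates(T = 96L, pre = 32L),
                          lambda_l = 30, lambda_p = 1)
  f <- fit_amplitudes_shifts(ei, pr$mu, pr)
  expect_gt(mean(colSums(f$amplitudes) == 0), 0.8)
})

test_that("fits are scale-covariant", {
  gt <- tiny_recovery(T = 64L, noise_sd = 1)
  s <- 3.7
  pr1 <- build_shape_prior(gt$cell$templates, lambda_l = 2, lambda_p = 1)
  pr2 <- build_shape_prior(gt$cell$templates, lambda_l = 2 * s,
                           lambda_p = s^2)
  ei2 <- electrical_image(s * gt$ei$data, gt$arr,
                          pre_samples = gt$ei$pre_samples)
  f1 <- fit_decomposition(gt$ei, pr1, max_iters = 3L)
  f2 <- fit_decomposition(ei2, pr2, max_iters = 3L)
  p1 <- fitted(f1); p2 <- fitted(f2)
  expect_equal(p2, s * p1, tolerance = 1e-5)
  expect_equal(f2$amplitudes, s * f1$amplitudes, tolerance = 1e-4)
})

test_that("reconstruct_ei matches the shift-superposition definition", {
  B <- stereotyped_templates(T = 48L, pre = 16L)
  arr <- hex_array(1, 30)
  A <- matrix(0, 3, arr$n); tau <- matrix(0L, 3, arr$n)
  A[2, 3] <- 1; tau[2, 3] <- 7L
  fit <- structure(list(waveforms = B, amplitudes = A, shifts = tau,
                        ei = electrical_image(matrix(0, 48, arr$n), arr,
                                              pre_samples = 16L)),
                   class = "ei_decomposition")
  rec <- reconstruct_ei(fit)
  expect_equal(rec$data[, 3], circ_shift(B[2, ], 7))
  expect_true(all(rec$data[, -3] == 0))
})

test_that("fit containers round-trip and methods behave", {
  gt <- tiny_recovery(T = 64L, noise_sd = 1)
  pr <- build_shape_prior(gt$cell$templates, lambda_l = 1, lambda_p = 1)
  fit <- fit_decomposition(gt$ei, pr, max_iters = 2L)
  expect_identical(coef(fit), fit$amplitudes)
  expect_equal(residuals(fit), gt$ei$data - fitted(fit))
  expect_s3_class(predict(fit), "electrical_image")
  s <- summary(fit)
  expect_true(s$rel_mse >= 0 && s$rel_mse < 1)
  path <- tempfile(fileext = ".json")
  write_fit(fit, path)
  back <- read_fit(path)
  expect_identical(back$waveforms, fit$waveforms)
  expect_identical(back$amplitudes, fit$amplitudes)
  expect_identical(back$shifts, fit$shifts)
  expect_output(print(fit), "ei_decomposition")
})
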