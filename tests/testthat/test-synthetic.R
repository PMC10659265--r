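test_that("stereotyped templates have the expected lobe structure", {
  B <- stereotyped_templates()
  # soma: strong early negative peak, later positive peak
  expect_lt(which.min(B[1, ]), which.max(B[1, ]))
  # dendrite: strong early positive peak, later negative peak
  expect_lt(which.max(B[2, ]), which.min(B[2, ]))
  # axon: triphasic (three lobes above 10% of peak, signs + - +)
  ax <- B[3, ]
  lab <- sign(ax) * (abs(ax) > 0.1)
  runs <- rle(lab[lab != 0])$values
  expect_identical(runs, c(1, -1, 1))
  # unit peak normalization
  expect_equal(unname(apply(abs(B), 1, max)), rep(1, 3))
})

test_that("synthetic EIs reproduce their ground truth exactly without noise", {
  arr <- hex_array(3, 60)
  cell <- synthesize_cell(arr, "OFF_midget", seed = 4)
  ei0 <- synthesize_cell_ei(cell, arr, noise_sd = 0)
  expect_equal(ei0$data,
               eidecomp:::reconstruct_matrix(cell$templates,
                                             cell$true_amplitudes,
                                             cell$true_shifts))
  e1 <- synthesize_cell_ei(cell, arr, noise_sd = 2, seed = 9)
  e2 <- synthesize_cell_ei(cell, arr, noise_sd = 2, seed = 9)
  expect_identical(e1$data, e2$data)
  expect_true(all(cell$true_amplitudes >= 0))
})

test_that("axonal shifts follow arc length over conduction velocity", {
  # an electrode 500 um along the axon at 1 m/s and 20 kHz lags 10 samples
  pos <- rbind(c(0, 0), c(500, 0), c(250, 40), c(0, 300), c(-100, 0),
               c(150, -80), c(350, 10))
  arr <- electrode_array(pos, 100, recenter = FALSE)
  cell <- synthesize_cell(arr, soma_xy = c(0, 0), axon_angle = 0,
                          conduction_velocity = 1, seed = 1)
  expect_identical(cell$true_shifts[3, 2], 10L)
  expect_identical(cell$true_shifts[3, 7], 7L)  # 350 um -> 0.35 ms
  # axonal shifts increase with distance along the path
  on_path <- which(cell$true_amplitudes[3, ] > 0)
  s_along <- pos[on_path, 1]
  expect_false(is.unsorted(cell$true_shifts[3, on_path][order(s_along)]))
})

test_that("mosaic lattices have the expected geometry and density", {
  arr <- rect_array(12, 12, 60)  # 660 x 660 um box
  cells <- synthesize_mosaic(arr, spacing = 120, jitter = 0, seed = 2)
  ctrs <- t(vapply(cells, function(cc) cc$dendritic_center_xy, numeric(2)))
  # exact lattice: nearest-neighbor distance equals the spacing
  d <- as.matrix(dist(ctrs)); diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(120, nrow(ctrs)), tolerance = 1e-9)
  # density ~ area / (s^2 sqrt(3)/2)
  area <- prod(apply(arr$positions, 2, function(v) diff(range(v))))
  expected <- area / (120^2 * sqrt(3) / 2)
  expect_lt(abs(nrow(ctrs) - expected) / expected, 0.35)
  # deterministic under seed
  cells2 <- synthesize_mosaic(arr, spacing = 120, jitter = 5, seed = 3)
  cells3 <- synthesize_mosaic(arr, spacing = 120, jitter = 5, seed = 3)
  expect_identical(vapply(cells2, function(cc) cc$dendritic_center_xy[1],
                          numeric(1)),
                   vapply(cells3, function(cc) cc$dendritic_center_xy[1],
                          numeric(1)))
})

test_that("preparation cohorts encode the intended type effects", {
  preps <- synthesize_preparation_set(n_preps = 4L, cells_per_type = 3L,
                                      seed = 1L)
  expect_length(preps, 4L)
  expect_length(preps[[1]]$cells, 12L)
  # parasols have larger somatic/dendritic amplitude norms than midgets
  recs <- typed_records(preps, seed = 1L)
  par <- grepl("parasol", recs$label)
  expect_gt(median(recs$norms[par, 1]), median(recs$norms[!par, 1]))
  expect_gt(median(recs$norms[par, 2]), median(recs$norms[!par, 2]))
  # reproducibility
  recs2 <- typed_records(synthesize_preparation_set(n_preps = 4L,
                                                    cells_per_type = 3L,
                                                    seed = 1L), seed = 1L)
  expect_identical(recs$norms, recs2$norms)
  # default cohort size matches the leave-one-out design
  expect_identical(formals(synthesize_preparation_set)$n_preps, 29L)
})

test_that("null effect sizes carry no type information", {
  eff0 <- effect_config(morph_strength = 0, amp_strength = 0)
  preps <- synthesize_preparation_set(n_preps = 4L, cells_per_type = 4L,
                                      effect = eff0, seed = 2L)
  recs <- typed_records(preps, effect = eff0, seed = 2L)
  # amplitude-norm rule performs at chance
  par <- grepl("parasol", recs$label)
  a <- amplitude_norm_auroc(recs$norms[, 2], par)
  expect_gt(a, 0.3); expect_lt(a, 0.7)
})

test_that("synthetic STAs are separable with the stated geometry", {
  arr <- hex_array(2, 30)
  cell <- synthesize_cell(arr, "ON_parasol", rf_center_xy = c(17.3, 22.8),
                          rf_sigma = 3, seed = 5)
  sta <- synthesize_sta(cell, nx = 40L, ny = 40L, noise_sd = 0)
  # center of mass of the peak-frame intensity equals the rf center
  pk <- which.max(apply(abs(sta), 3, max))
  w <- abs(sta[, , pk])
  cx <- sum(((1:40) - 0.5) * rowSums(w)) / sum(w)
  cy <- sum(((1:40) - 0.5) * colSums(w)) / sum(w)
  expect_equal(c(cx, cy), c(17.3, 22.8), tolerance = 1e-6)
  # symmetric about the center (whole-pixel reflection around pixel 20)
  offj <- abs(sta[, 20 - 3, pk]); onj <- abs(sta[, 20 + 3, pk])
  expect_gt(cor(offj, onj), 0.99)
  # OFF cells flip sign
  cello <- synthesize_cell(arr, "OFF_midget", rf_center_xy = c(20, 20),
                           rf_sigma = 3, seed = 5)
  stao <- synthesize_sta(cello, nx = 40L, ny = 40L, noise_sd = 0)
  pko <- which.max(apply(abs(stao), 3, max))
  expect_lt(min(stao[, , pko]), 0)
  expect_identical(synthesize_sta(cell, noise_sd = 0.1, seed = 3),
                   synthesize_sta(cell, noise_sd = 0.1, seed = 3))
})

test_that("recovery benchmark EIs reconstruct exactly at zero noise", {
  gt <- synthesize_recovery_ei(hex_array(2, 30), T = 60L, pre = 20L,
                               noise_frac = 0, seed = 3)
  expect_equal(gt$ei$data,
               eidecomp:::reconstruct_matrix(gt$templates, gt$amplitudes,
                                             gt$shifts))
})
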