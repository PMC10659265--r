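test_that("auroc equals rank/pair-counting definitions", {
  expect_equal(auroc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auroc(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  set.seed(15)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # plenty of ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("amplitude-norm rules are antisymmetric and direction-faithful", {
  set.seed(16)
  norms <- c(rnorm(20, 10), rnorm(20, 5))
  labels <- rep(c(TRUE, FALSE), each = 20)
  a1 <- amplitude_norm_auroc(norms, labels, "positive_larger")
  a2 <- amplitude_norm_auroc(norms, labels, "positive_smaller")
  expect_equal(a1 + a2, 1)
  expect_gt(a1, 0.9)
  # a population violating the rule scores below 0.5 and is reported as-is
  expect_lt(amplitude_norm_auroc(norms, !labels, "positive_larger"), 0.5)
})

test_that("FWHM measurement and rescaling behave on analytic waveforms", {
  tt <- 1:200
  w <- -exp(-(tt - 100)^2 / (2 * 8^2))
  expect_equal(fwhm_negative(w), 2 * sqrt(2 * log(2)) * 8, tolerance = 0.02)
  expect_error(fwhm_negative(abs(w)), "negative")

  # stretching the time axis scales the FWHM
  w2 <- -exp(-(tt - 100)^2 / (2 * 16^2))
  s <- eidecomp:::stretch_waveform(w2, 0.5, 100)
  expect_equal(fwhm_negative(s), fwhm_negative(w), tolerance = 0.05)
  expect_gt(cor(s, w), 0.999)
})

test_that("per-preparation FWHM rescaling equalizes somatic time scales", {
  preps <- synthesize_preparation_set(n_preps = 3L, cells_per_type = 3L,
                                      effect = effect_config(
                                        prep_time_scale_sd = 0.25,
                                        cell_waveform_noise = 0.01),
                                      seed = 4L)
  recs <- typed_records(preps, effect = effect_config(cell_waveform_noise = 0.01),
                        seed = 4L)
  res <- rescale_waveforms_fwhm(recs)
  ref <- attr(res, "reference_fwhm")
  for (p in levels(res$prep)) {
    sel <- res$prep == p & res$label == "OFF_parasol"
    msoma <- Reduce(`+`, lapply(res$waveforms[sel], function(w) w[1, ])) /
      sum(sel)
    expect_lt(abs(fwhm_negative(msoma) - ref), 0.6)  # within half a sample
  }
  # a preparation already at the reference is unchanged
  one <- rescale_waveforms_fwhm(recs, reference_fwhm = NULL)
  f1 <- attr(one, "stretch_factors")[1]
  expect_equal(unname(f1), 1, tolerance = 1e-9)
})

test_that("waveform alignment lands landmarks on the target index", {
  B <- stereotyped_templates(T = 120L, pre = 40L)
  # aligning an aligned waveform is the identity (idempotence)
  a1 <- align_waveform(B[1, ], "soma")
  expect_equal(align_waveform(a1, "soma"), a1)
  # a rolled waveform comes back
  expect_equal(align_waveform(circ_shift(B[1, ], 7), "soma"), a1)
  expect_equal(align_waveform(circ_shift(B[2, ], -9), "dendrite"),
               align_waveform(B[2, ], "dendrite"))
  # axonal alignment puts the absolute minimum at the target
  ax <- align_waveform(circ_shift(B[3, ], 13), "axon")
  expect_identical(which.min(ax), 60L)
  # matrix form aligns each row by its compartment
  M <- align_waveform(B)
  expect_equal(M[1, ], a1)
})

test_that("waveform PCA separates distinct template families", {
  B1 <- stereotyped_templates(T = 100L, pre = 33L)
  B2 <- stereotyped_templates(T = 100L, pre = 33L,
                              morph = list(width = c(1.5, 1, 1),
                                           ratio = c(0.6, 1, 1)))
  wl <- c(replicate(10, B1 + matrix(rnorm(300, 0, 0.02), 3), simplify = FALSE),
          replicate(10, B2 + matrix(rnorm(300, 0, 0.02), 3), simplify = FALSE))
  recs <- structure(list(waveforms = wl, norms = matrix(1, 20, 3),
                         label = factor(rep(c("a", "b"), each = 10)),
                         prep = factor(rep("p1", 20))),
                    class = "typed_records")
  pc <- waveform_pca(recs, "soma")
  expect_identical(ncol(pc$scores), 2L)
  between <- abs(mean(pc$scores[1:10, 1]) - mean(pc$scores[11:20, 1]))
  within <- mean(c(sd(pc$scores[1:10, 1]), sd(pc$scores[11:20, 1])))
  expect_gt(between, 3 * within)

  # identical waveforms -> all scores zero
  rec0 <- recs; rec0$waveforms <- replicate(20, B1, simplify = FALSE)
  expect_lt(max(abs(waveform_pca(rec0, 1)$scores)), 1e-10)
})

test_that("logistic training-set separability behaves at the extremes", {
  set.seed(17)
  X <- rbind(matrix(rnorm(200, 0), 10), matrix(rnorm(200, 3), 10))
  y <- rep(c(FALSE, TRUE), each = 10)
  expect_equal(logistic_separability_auroc(X, y), 1.0)
  # duplicating every sample leaves training AUROC unchanged
  expect_equal(logistic_separability_auroc(rbind(X, X), c(y, y)), 1.0)
  expect_error(logistic_separability_auroc(X, rep(TRUE, 20)), "both classes")
})

test_that("feature tables have the documented layout and invariants", {
  preps <- synthesize_preparation_set(n_preps = 3L, cells_per_type = 3L,
                                      seed = 6L)
  recs <- typed_records(preps, seed = 6L)
  ft <- build_feature_table(recs)
  expect_identical(ncol(ft$X), 3L * 180L + 3L)  # 543 at T = 180
  # z-scored norms: per-preparation mean 0, SD 1
  zn <- ft$X[, 541:543]
  for (p in levels(ft$prep)) {
    sel <- ft$prep == p
    expect_lt(max(abs(colMeans(zn[sel, ]))), 1e-10)
    expect_lt(max(abs(apply(zn[sel, ], 2, sd) - 1)), 1e-10)
  }
})

test_that("the classifier network is reproducible and learns separable data", {
  set.seed(18)
  n <- 240
  X <- matrix(rnorm(n * 10), n, 10)
  cls <- sample(1:4, n, replace = TRUE)
  X[cbind(seq_len(n), cls)] <- X[cbind(seq_len(n), cls)] + 4
  y <- factor(c("a", "b", "c", "d")[cls])
  m1 <- train_type_classifier(X, y, seed = 5L)
  m2 <- train_type_classifier(X, y, seed = 5L)
  p1 <- predict(m1, X); p2 <- predict(m2, X)
  expect_identical(p1, p2)
  expect_gt(mean(colnames(p1)[max.col(p1)] == as.character(y)), 0.95)
  expect_equal(rowSums(p1), rep(1, n), tolerance = 1e-12)
  expect_error(train_type_classifier(X, factor(rep("a", n))), "2 classes")
})

test_that("classifier metrics respect their definitions", {
  types <- c("ON_parasol", "OFF_parasol", "ON_midget", "OFF_midget")
  set.seed(19)
  truth <- factor(sample(types, 40, TRUE), levels = types)
  prob <- matrix(runif(160), 40, 4, dimnames = list(NULL, types))
  prob <- prob / rowSums(prob)
  m <- classifier_metrics(prob, truth)
  # coarsening correct events can only help
  expect_gte(m$parasol_vs_midget_accuracy, m$four_way_accuracy)
  expect_true(all(unlist(m) >= 0 & unlist(m) <= 1, na.rm = TRUE))
  # perfect probabilities give perfect metrics
  hot <- matrix(0, 40, 4, dimnames = list(NULL, types))
  hot[cbind(seq_len(40), as.integer(truth))] <- 1
  mh <- classifier_metrics(0.97 * hot + 0.01, truth)
  expect_equal(mh$four_way_accuracy, 1)
  expect_equal(mh$on_off_midget_auroc, 1)
})

test_that("leave-one-out evaluation returns one row per preparation", {
  preps <- synthesize_preparation_set(n_preps = 3L, cells_per_type = 3L,
                                      seed = 7L)
  recs <- typed_records(preps, seed = 7L)
  m <- leave_one_out_eval(recs, seed = 1L, epochs = 5L)
  expect_identical(nrow(m), 3L)
  expect_identical(sort(as.character(m$prep)), sort(levels(recs$prep)))
})
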