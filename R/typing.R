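#' Full width at half maximum of the negative phase
#'
#' Width (in samples, sub-sample by linear interpolation) of the negative
#' lobe of a waveform at half its minimum value.
#'
#' @param w numeric waveform
#' @return FWHM in samples
#' @export
fwhm_negative <- function(w) {
  m <- min(w)
  if (m >= 0) stop("waveform has no negative phase")
  half <- m / 2
  i0 <- which.min(w)
  # walk outwards to the half-minimum crossings
  left <- i0
  while (left > 1 && w[left - 1] <= half) left <- left - 1
  xl <- if (left == 1) 1 else {
    (left - 1) + (half - w[left - 1]) / (w[left] - w[left - 1])
  }
  right <- i0
  n <- length(w)
  while (right < n && w[right + 1] <= half) right <- right + 1
  xr <- if (right == n) n else {
    right + (half - w[right]) / (w[right + 1] - w[right])
  }
  xr - xl
}

# resample w on a time axis stretched by `factor` about `anchor`
# (factor > 1 widens); cubic spline interpolation, zero outside the window
stretch_waveform <- function(w, factor, anchor) {
  T <- length(w)
  src <- anchor + ((seq_len(T)) - anchor) / factor
  f <- stats::splinefun(seq_len(T), w, method = "natural")
  out <- f(src)
  out[src < 1 | src > T] <- 0
  out
}

#' Rescale waveforms to a common somatic time scale
#'
#' Equalizes waveform time scales across preparations: for each
#' preparation, the full-width half-maximum of the negative phase of the
#' mean OFF parasol somatic waveform is measured, and a single scalar time
#' stretch `reference_fwhm / measured_fwhm` is applied (spline
#' interpolation and resampling) to every waveform of that preparation.
#' The reference defaults to the first preparation in the pooled set.
#'
#' @param records a `typed_records` object
#' @param reference_fwhm reference FWHM in samples (default: first
#'   preparation's measured value)
#' @param anchor_type the type whose mean somatic waveform defines the
#'   time scale (default `"OFF_parasol"`)
#' @return the records with rescaled `waveforms`, plus attributes
#'   `stretch_factors` and `reference_fwhm`
#' @export
rescale_waveforms_fwhm <- function(records, reference_fwhm = NULL,
                                   anchor_type = "OFF_parasol") {
  preps <- levels(records$prep)
  measured <- numeric(length(preps)); anchors <- numeric(length(preps))
  for (i in seq_along(preps)) {
    sel <- records$prep == preps[i] & records$label == anchor_type
    if (!any(sel)) stop(sprintf("preparation %s has no %s cells", preps[i],
                                anchor_type))
    msoma <- Reduce(`+`, lapply(records$waveforms[sel], function(w) w[1, ])) /
      sum(sel)
    measured[i] <- fwhm_negative(msoma)
    anchors[i] <- which.min(msoma)
  }
  if (is.null(reference_fwhm)) reference_fwhm <- measured[1]
  factors <- reference_fwhm / measured
  out <- records
  for (i in seq_along(preps)) {
    sel <- which(records$prep == preps[i])
    for (j in sel) {
      out$waveforms[[j]] <- t(apply(records$waveforms[[j]], 1,
                                    stretch_waveform, factor = factors[i],
                                    anchor = anchors[i]))
    }
  }
  attr(out, "stretch_factors") <- stats::setNames(factors, preps)
  attr(out, "reference_fwhm") <- reference_fwhm
  out
}

#' Temporally align a compartment waveform
#'
#' Somatic and dendritic waveforms are circularly shifted so the principal
#' zero-crossing — the sign change between the two largest-magnitude
#' opposite-sign lobes — lands at a fixed index; axonal waveforms are
#' shifted so the absolute minimum lands there. Sub-sample crossing
#' positions are located by linear interpolation and rounded to the
#' nearest integer shift, so alignment is idempotent.
#'
#' @param w length-T waveform (or C x T matrix: rows aligned by their
#'   compartment, ordered soma, dendrite, axon)
#' @param compartment `"soma"`, `"dendrite"` or `"axon"` (vector fallback)
#' @param target_index index the landmark is moved to (default `T %/% 2`)
#' @return aligned waveform (same shape as input)
#' @export
align_waveform <- function(w, compartment = c("soma", "dendrite", "axon"),
                           target_index = NULL) {
  if (is.matrix(w)) {
    comps <- c("soma", "dendrite", "axon")[seq_len(nrow(w))]
    return(t(vapply(seq_len(nrow(w)),
                    function(c) align_waveform(w[c, ], comps[c], target_index),
                    numeric(ncol(w)))))
  }
  compartment <- match.arg(compartment)
  T <- length(w)
  if (is.null(target_index)) target_index <- T %/% 2
  landmark <- if (compartment == "axon") {
    which.min(w)
  } else {
    i_neg <- which.min(w); i_pos <- which.max(w)
    lo <- min(i_neg, i_pos); hi <- max(i_neg, i_pos)
    seg <- w[lo:hi]
    cross <- which(seg[-length(seg)] * seg[-1] <= 0 & seg[-length(seg)] != 0)
    if (length(cross) == 0L) {
      lo  # degenerate (single-signed) waveform: fall back to the first lobe
    } else {
      i <- lo + cross[1] - 1
      frac <- w[i] / (w[i] - w[i + 1])
      round(i + frac)
    }
  }
  circ_shift(w, target_index - landmark)
}

#' Principal components of pooled basis waveforms
#'
#' Per-compartment PCA of (typically aligned) basis waveforms pooled
#' across preparations; the top components summarize systematic waveform
#' shape variation between cell types.
#'
#' @param records a `typed_records` object (waveforms should be aligned)
#' @param compartment 1 = soma, 2 = dendrite, 3 = axon (or name)
#' @param n_components number of components to return (default 2)
#' @return list with `scores` (n x n_components), `rotation`, `sdev`,
#'   `label`, `prep`
#' @export
waveform_pca <- function(records, compartment = 1L, n_components = 2L) {
  if (is.character(compartment)) {
    compartment <- match(compartment, c("soma", "dendrite", "axon"))
  }
  M <- t(vapply(records$waveforms, function(w) w[compartment, ],
                numeric(ncol(records$waveforms[[1]]))))
  pc <- prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       sdev = pc$sdev, label = records$label, prep = records$prep)
}

#' Area under the ROC curve
#'
#' Rank-based AUROC, equal to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`; ties contribute 1/2. Equals the probability that a
#' random positive outscores a random negative.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels logical (or 0/1) class labels
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("auroc needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Training-set separability of ON vs OFF cells by waveform shape
#'
#' Fits a linear logistic classifier on single-compartment waveforms (one
#' sample per time point as features) and reports the AUROC of its scores
#' on the training data — an upper-bound style separability measure, not a
#' generalization estimate.
#'
#' @param waveforms n x T matrix (one aligned compartment waveform per row)
#' @param labels logical vector (e.g. TRUE = ON)
#' @return training AUROC
#' @export
logistic_separability_auroc <- function(waveforms, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  X <- cbind(1, as.matrix(waveforms))
  fit <- suppressWarnings(stats::glm.fit(X, as.numeric(labels),
                                         family = binomial()))
  auroc(fit$linear.predictors, labels)
}

#' AUROC of an anatomy-derived amplitude-norm decision rule
#'
#' Scores cells by a compartment amplitude norm and evaluates the fixed
#' decision rule "the positive class has the larger norm" (or smaller,
#' when `rule = "positive_smaller"`). No refitting is done: if the rule's
#' direction is wrong for the data, the AUROC falls below 0.5 and is
#' reported as-is, so values span the full `[0, 1]` range.
#'
#' @param norms numeric amplitude norms
#' @param labels logical labels (TRUE = the class the rule calls larger)
#' @param rule `"positive_larger"` (default) or `"positive_smaller"`
#' @return AUROC in `[0, 1]`
#' @export
amplitude_norm_auroc <- function(norms, labels,
                                 rule = c("positive_larger", "positive_smaller")) {
  rule <- match.arg(rule)
  s <- if (rule == "positive_larger") norms else -norms
  auroc(s, labels)
}

#' Z-score compartment norms within preparations
#'
#' @param norms n x 3 matrix of compartment amplitude L2 norms
#' @param prep factor of preparation ids
#' @return n x 3 matrix with per-preparation column mean 0 and SD 1
#' @export
zscore_norms <- function(norms, prep) {
  out <- norms
  for (p in levels(factor(prep))) {
    sel <- prep == p
    for (j in seq_len(ncol(norms))) {
      v <- norms[sel, j]
      s <- sd(v)
      out[sel, j] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
    }
  }
  out
}

#' Classifier feature table
#'
#' Builds the classifier input for each cell: the three aligned (not
#' temporally rescaled) basis waveforms concatenated in fixed order (soma,
#' dendrite, axon) followed by the three compartment amplitude norms
#' z-scored within each preparation. With T = 180 samples the feature
#' vector has length 3 * 180 + 3 = 543.
#'
#' @param records a `typed_records` object
#' @return list with `X` (n x (3T + 3) matrix), `label`, `prep`
#' @export
build_feature_table <- function(records) {
  zn <- zscore_norms(records$norms, records$prep)
  Xw <- t(vapply(records$waveforms,
                 function(w) as.numeric(t(align_waveform(w))),
                 numeric(length(records$waveforms[[1]]))))
  list(X = cbind(Xw, zn), label = records$label, prep = records$prep)
}

## ---- small feed-forward classifier -------------------------------------

relu <- function(x) (x > 0) * x

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

adam_update <- function(state, name, grad, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  m <- b1 * state$m[[name]] + (1 - b1) * grad
  v <- b2 * state$v[[name]] + (1 - b2) * grad^2
  state$m[[name]] <- m
  state$v[[name]] <- v
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  state$par[[name]] <- state$par[[name]] - lr * mh / (sqrt(vh) + eps)
  state
}

#' Train the cell-type classifier network
#'
#' Feed-forward network with three hidden layers of 25 units, each with a
#' ReLU nonlinearity and batch normalization, and a 4-unit softmax output
#' ("four layers" counted as hidden + output). Trained with cross-entropy
#' loss by mini-batch gradient descent for 30 epochs with batch size 32
#' and the Adam optimizer (learning rate 1e-3). Batch-norm statistics are
#' accumulated as running averages during training and frozen at
#' evaluation. Reproducible given `seed`.
#'
#' @param X n x d feature matrix (see [build_feature_table()])
#' @param y factor of class labels (>= 2 classes)
#' @param seed integer seed (weight init and batch shuffling)
#' @param epochs,batch_size,lr training hyperparameters
#' @param hidden hidden layer widths (default `c(25, 25, 25)`)
#' @return a `type_classifier` model object
#' @export
train_type_classifier <- function(X, y, seed = 0L, epochs = 30L,
                                  batch_size = 32L, lr = 1e-3,
                                  hidden = c(25L, 25L, 25L)) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2L) stop("training data must contain at least 2 classes")
  n <- nrow(X); d <- ncol(X); K <- length(classes)
  sizes <- c(d, hidden, K)
  L <- length(hidden)
  Y <- matrix(0, K, n); Y[cbind(as.integer(y), seq_len(n))] <- 1
  Xt <- t(X)  # d x n

  par <- list()
  withr_seed(seed, {
    for (l in seq_len(L + 1)) {
      par[[paste0("W", l)]] <- matrix(rnorm(sizes[l + 1] * sizes[l],
                                            0, sqrt(2 / sizes[l])),
                                      sizes[l + 1], sizes[l])
      par[[paste0("b", l)]] <- numeric(sizes[l + 1])
      if (l <= L) {
        par[[paste0("g", l)]] <- rep(1, sizes[l + 1])
        par[[paste0("beta", l)]] <- numeric(sizes[l + 1])
      }
    }
  })
  state <- list(par = par,
                m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  run_mean <- lapply(hidden, numeric)
  run_var <- lapply(hidden, function(h) rep(1, h))
  eps_bn <- 1e-5; mom <- 0.9; t_adam <- 0

  batches_of <- function(ord) {
    split(ord, ceiling(seq_along(ord) / batch_size))
  }
  withr_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (idx in batches_of(ord)) {
        m_b <- length(idx)
        H <- Xt[, idx, drop = FALSE]
        cache <- list()
        p <- state$par
        for (l in seq_len(L)) {
          Z <- p[[paste0("W", l)]] %*% H + p[[paste0("b", l)]]
          mu <- rowMeans(Z)
          va <- rowMeans((Z - mu)^2)
          run_mean[[l]] <- mom * run_mean[[l]] + (1 - mom) * mu
          run_var[[l]] <- mom * run_var[[l]] + (1 - mom) * va
          inv <- 1 / sqrt(va + eps_bn)
          Zh <- (Z - mu) * inv
          ZB <- Zh * p[[paste0("g", l)]] + p[[paste0("beta", l)]]
          Hn <- relu(ZB)
          cache[[l]] <- list(H = H, Zh = Zh, inv = inv, ZB = ZB)
          H <- Hn
        }
        O <- p[[paste0("W", L + 1)]] %*% H + p[[paste0("b", L + 1)]]
        P <- softmax_cols(O)
        dO <- (P - Y[, idx, drop = FALSE]) / m_b
        t_adam <- t_adam + 1
        gW <- dO %*% t(H); gb <- rowSums(dO)
        dH <- t(state$par[[paste0("W", L + 1)]]) %*% dO
        state <- adam_update(state, paste0("W", L + 1), gW, lr, t_adam)
        state <- adam_update(state, paste0("b", L + 1), gb, lr, t_adam)
        for (l in rev(seq_len(L))) {
          cc <- cache[[l]]
          dZB <- dH * (cc$ZB > 0)
          gg <- rowSums(dZB * cc$Zh)
          gbeta <- rowSums(dZB)
          dZh <- dZB * state$par[[paste0("g", l)]]
          # batch-norm backward (per unit, over the batch dimension)
          dZ <- cc$inv / m_b *
            (m_b * dZh - rowSums(dZh) - cc$Zh * rowSums(dZh * cc$Zh))
          gW <- dZ %*% t(cc$H); gb <- rowSums(dZ)
          dH <- t(state$par[[paste0("W", l)]]) %*% dZ
          state <- adam_update(state, paste0("g", l), gg, lr, t_adam)
          state <- adam_update(state, paste0("beta", l), gbeta, lr, t_adam)
          state <- adam_update(state, paste0("W", l), gW, lr, t_adam)
          state <- adam_update(state, paste0("b", l), gb, lr, t_adam)
        }
      }
    }
  })
  structure(list(par = state$par, run_mean = run_mean, run_var = run_var,
                 hidden = hidden, classes = classes, eps_bn = eps_bn),
            class = "type_classifier")
}

#' @export
print.type_classifier <- function(x, ...) {
  cat(sprintf("<type_classifier> %s -> %s -> %d classes (%s)\n",
              ncol(x$par$W1), paste(x$hidden, collapse = "-"),
              length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param object a [train_type_classifier()] model
#' @param newdata n x d feature matrix
#' @param ... unused
#' @return n x K matrix of class probabilities (columns named by class)
#' @export
predict.type_classifier <- function(object, newdata, ...) {
  H <- t(as.matrix(newdata))
  L <- length(object$hidden)
  p <- object$par
  for (l in seq_len(L)) {
    Z <- p[[paste0("W", l)]] %*% H + p[[paste0("b", l)]]
    Zh <- (Z - object$run_mean[[l]]) / sqrt(object$run_var[[l]] + object$eps_bn)
    H <- relu(Zh * p[[paste0("g", l)]] + p[[paste0("beta", l)]])
  }
  P <- softmax_cols(p[[paste0("W", L + 1)]] %*% H + p[[paste0("b", L + 1)]])
  P <- t(P)
  colnames(P) <- object$classes
  P
}

is_parasol <- function(lbl) grepl("parasol$", lbl)
is_on <- function(lbl) grepl("^ON", lbl)

#' Classification metrics for one evaluation set
#'
#' Computes the evaluation metrics: four-way accuracy; class-weighted
#' one-vs-rest AUROC; parasol-vs-midget accuracy (correct if the predicted
#' type has the right parasol/midget coarse class) and AUROC of the summed
#' parasol probability; and ON-vs-OFF accuracy/AUROC within parasols and
#' within midgets, using the conditional probability of the ON type given
#' the coarse class.
#'
#' @param prob n x 4 probability matrix with columns named by type
#' @param truth factor of true types
#' @return one-row data frame of metrics (AUROCs are NA when a
#'   sub-problem has a single class in `truth`)
#' @export
classifier_metrics <- function(prob, truth) {
  truth <- as.character(truth)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  four_acc <- mean(pred == truth)
  n <- length(truth)
  wa <- 0
  for (k in colnames(prob)) {
    nk <- sum(truth == k)
    if (nk == 0L || nk == n) next
    wa <- wa + nk / n * auroc(prob[, k], truth == k)
  }
  p_par <- rowSums(prob[, is_parasol(colnames(prob)), drop = FALSE])
  pm_acc <- mean(is_parasol(pred) == is_parasol(truth))
  pm_auc <- if (length(unique(is_parasol(truth))) == 2L) {
    auroc(p_par, is_parasol(truth))
  } else NA_real_
  onoff <- function(coarse) {
    sel <- (if (coarse == "parasol") is_parasol(truth) else !is_parasol(truth))
    if (!any(sel)) return(c(NA_real_, NA_real_))
    cols <- colnames(prob)[if (coarse == "parasol") is_parasol(colnames(prob))
                           else !is_parasol(colnames(prob))]
    on_col <- cols[is_on(cols)]; off_col <- cols[!is_on(cols)]
    cond <- prob[sel, on_col] / (prob[sel, on_col] + prob[sel, off_col])
    acc <- mean((cond > 0.5) == is_on(truth[sel]))
    auc <- if (length(unique(is_on(truth[sel]))) == 2L) {
      auroc(cond, is_on(truth[sel]))
    } else NA_real_
    c(acc, auc)
  }
  par <- onoff("parasol"); mid <- onoff("midget")
  data.frame(four_way_accuracy = four_acc, four_way_weighted_ovr_auroc = wa,
             parasol_vs_midget_accuracy = pm_acc,
             parasol_vs_midget_auroc = pm_auc,
             on_off_parasol_accuracy = par[1], on_off_parasol_auroc = par[2],
             on_off_midget_accuracy = mid[1], on_off_midget_auroc = mid[2])
}

#' Classification accuracy versus EI spike count
#'
#' Evaluates how cell-type classification degrades with EI signal-to-noise
#' ratio: decompositions are refit to EIs recomputed at each effective
#' spike count (EI noise scales as `1 / sqrt(n_spikes)`), and each held-out
#' preparation is scored with the leave-one-out network trained once on the
#' other preparations' full-spike-count (reference) decompositions — the
#' classifier is not retrained per noise level, so the trend isolates
#' feature degradation.
#'
#' @param preps a [synthesize_preparation_set()] cohort
#' @param spike_counts increasing effective spike counts; the largest is
#'   the reference level used for training
#' @param base_noise_sd single-trace noise SD (uV)
#' @param seed integer seed
#' @param ... forwarded to [decompose_preparation()]
#' @return data frame with `n_spikes` and pooled `accuracy`
#' @export
snr_accuracy_trend <- function(preps, spike_counts = c(100, 1000, 10000),
                               base_noise_sd = 600, seed = 0L, ...) {
  spike_counts <- sort(spike_counts)
  recs_by <- lapply(seq_along(spike_counts), function(l) {
    bind_records(lapply(seq_along(preps), function(p) {
      decompose_preparation(preps[[p]], n_spikes = spike_counts[l],
                            base_noise_sd = base_noise_sd,
                            seed = seed + 1000L * p + l, ...)
    }))
  })
  ft_by <- lapply(recs_by, build_feature_table)
  ref <- ft_by[[length(spike_counts)]]
  prep_ids <- levels(factor(ref$prep))
  correct <- matrix(0, length(spike_counts), 2)  # hits, total
  for (i in seq_along(prep_ids)) {
    tr <- ref$prep != prep_ids[i]
    model <- train_type_classifier(ref$X[tr, , drop = FALSE],
                                   droplevels(ref$label[tr]),
                                   seed = seed + i)
    for (l in seq_along(spike_counts)) {
      ho <- ft_by[[l]]$prep == prep_ids[i]
      prob <- predict(model, ft_by[[l]]$X[ho, , drop = FALSE])
      pred <- colnames(prob)[max.col(prob, ties.method = "first")]
      correct[l, 1] <- correct[l, 1] +
        sum(pred == as.character(ft_by[[l]]$label[ho]))
      correct[l, 2] <- correct[l, 2] + sum(ho)
    }
  }
  data.frame(n_spikes = spike_counts,
             accuracy = correct[, 1] / correct[, 2])
}

#' Leave-one-preparation-out classification
#'
#' For each preparation, trains the classifier network on all other
#' preparations and evaluates it on the held-out one, mimicking cell-type
#' identification in a novel retina. Only the supplied (major-type)
#' records are used.
#'
#' @param records a `typed_records` object (or a [build_feature_table()]
#'   result)
#' @param seed integer seed (a distinct derived seed per fold)
#' @param ... forwarded to [train_type_classifier()]
#' @return data frame with one row of [classifier_metrics()] per held-out
#'   preparation (plus the preparation id)
#' @export
leave_one_out_eval <- function(records, seed = 0L, ...) {
  feats <- if (!is.null(records$X)) records else build_feature_table(records)
  preps <- levels(factor(feats$prep))
  rows <- lapply(seq_along(preps), function(i) {
    ho <- feats$prep == preps[i]
    model <- train_type_classifier(feats$X[!ho, , drop = FALSE],
                                   droplevels(feats$label[!ho]),
                                   seed = seed + i, ...)
    prob <- predict(model, feats$X[ho, , drop = FALSE])
    cbind(data.frame(prep = preps[i]),
          classifier_metrics(prob, feats$label[ho]))
  })
  do.call(rbind, rows)
}
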