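#' Shift-search configuration
#'
#' Controls the per-electrode search over integer time-shift combinations.
#' The default coarse-to-fine schedule builds per-compartment candidate
#' shifts from a coarse grid (stride 8 samples over the allowed range)
#' *augmented by the `n_corr` best shifts by matched-filter correlation
#' between the compartment waveform and the electrode trace* (a blind
#' coarse grid alone misses the narrow correlation peaks of brief spike
#' waveforms), evaluates all combinations of those candidates, keeps the
#' best `n_keep` combinations by subproblem objective, and refines with
#' stride halving (4 -> 2 -> 1) in a +/- stride window around the
#' survivors. An exhaustive mode that scores every combination in the
#' range is available for validation; it is exact but only practical for
#' short windows or narrow ranges.
#'
#' Shift ranges are inclusive integer windows per compartment, interpreted
#' mod T when applied; `NULL` means the full window `[0, T)`. Narrowing the
#' ranges (e.g. a wide range for the propagating axonal compartment only)
#' is a pure speed optimization.
#'
#' In coarse mode, electrodes whose total combination count does not exceed
#' `auto_exhaustive` are enumerated exactly instead — the heuristic
#' schedule exists for search spaces where enumeration is unaffordable.
#' Set `auto_exhaustive = 0` to force the heuristic everywhere (used when
#' benchmarking the schedule itself).
#'
#' @param mode `"coarse"` (default) or `"exhaustive"`
#' @param stride coarse grid stride in samples (default 8)
#' @param n_keep number of surviving shift combinations carried through
#'   refinement (default 10)
#' @param n_corr number of correlation-guided candidate shifts per
#'   compartment added to the coarse grid (default 12)
#' @param ranges optional list of C length-2 integer vectors `c(lo, hi)`
#' @param auto_exhaustive combination-count budget below which the search
#'   enumerates exactly (default 40000)
#' @return a `shift_search` configuration object
#' @export
shift_search <- function(mode = c("coarse", "exhaustive"), stride = 8L,
                         n_keep = 10L, n_corr = 12L, ranges = NULL,
                         auto_exhaustive = 40000) {
  mode <- match.arg(mode)
  structure(list(mode = mode, stride = as.integer(stride),
                 n_keep = as.integer(n_keep), n_corr = as.integer(n_corr),
                 ranges = ranges, auto_exhaustive = auto_exhaustive),
            class = "shift_search")
}

search_bounds <- function(search, C, T) {
  lo <- integer(C); hi <- integer(C)
  for (c in seq_len(C)) {
    r <- if (!is.null(search$ranges)) search$ranges[[c]] else c(0L, T - 1L)
    lo[c] <- as.integer(r[1]); hi[c] <- as.integer(r[2])
    if (hi[c] < lo[c]) stop("shift range must have hi >= lo")
  }
  list(lo = lo, hi = hi)
}

#' Fit amplitudes and shifts for a single electrode
#'
#' Finds, for one electrode trace, the shift combination and nonnegative
#' amplitudes minimizing
#' `0.5 * ||sum_c a_c shift(B_c, tau_c) - x||^2 + lambda * (||a_{soma,dend}|| + |a_axon|)`
#' over the searched shift set, using the coarse-to-fine schedule (or
#' exhaustively) with the FISTA subproblem solver at each candidate.
#'
#' @param x length-T electrode trace
#' @param B C x T basis waveform matrix
#' @param lambda sparsity weight
#' @param search a [shift_search()] configuration
#' @param prev_tau optional length-C previous shifts, always included among
#'   the candidates (warm start; guarantees monotone alternating fits)
#' @return list with `amplitudes` (length C), `shifts` (length C, in
#'   `[0, T)`), and `objective` (the attained subproblem value)
#' @export
fit_shifts_amplitudes_electrode <- function(x, B, lambda = 0,
                                            search = shift_search(),
                                            prev_tau = NULL) {
  B <- as.matrix(B)
  res <- fit_amplitudes_shifts_matrix(matrix(x, ncol = 1), B, lambda, search,
                                      if (!is.null(prev_tau)) matrix(as.integer(prev_tau), ncol = 1) else NULL)
  list(amplitudes = drop(res$amplitudes), shifts = drop(res$shifts),
       objective = res$objective[1])
}

# internal: matrix-level amplitude/shift fit (X is T x N)
fit_amplitudes_shifts_matrix <- function(X, B, lambda, search, prev_tau = NULL) {
  C <- nrow(B); T <- ncol(B)
  if (ncol(as.matrix(X)) == 0L) stop("no electrodes")
  dead <- rowSums(B^2) == 0
  if (any(dead)) {
    warning(sprintf("basis row(s) %s are all zero; their amplitudes are forced to 0",
                    paste(which(dead), collapse = ",")))
  }
  b <- search_bounds(search, C, T)
  pv <- if (is.null(prev_tau)) matrix(0L, 0, 0) else prev_tau
  res <- cpp_fit_electrodes(as.matrix(X), B, lambda, c(0L, 0L, 1L)[seq_len(C)],
                            b$lo, b$hi, search$mode == "exhaustive",
                            search$stride, search$n_keep,
                            search$n_corr %||% 12L,
                            search$auto_exhaustive %||% 40000, pv,
                            1e-8, 300L, 1e-12, 5000L)
  res$shifts <- matrix(as.integer(res$shifts), C, ncol(as.matrix(X)))
  res
}

#' Fit amplitudes and shifts for a whole EI
#'
#' Applies [fit_shifts_amplitudes_electrode()] independently to every
#' electrode of the EI (the subproblems are separable across electrodes, so
#' results do not depend on electrode order and the step parallelizes
#' trivially).
#'
#' @param ei an [electrical_image()]
#' @param B C x T basis waveform matrix
#' @param prior a [build_shape_prior()] (supplies `lambda_l`)
#' @param search a [shift_search()]
#' @param prev_tau optional C x N previous shift matrix (warm start)
#' @return list with `amplitudes` (C x N), `shifts` (C x N),
#'   `objective` (total data + sparsity objective over electrodes)
#' @export
fit_amplitudes_shifts <- function(ei, B, prior, search = shift_search(),
                                  prev_tau = NULL) {
  res <- fit_amplitudes_shifts_matrix(ei$data, B, prior$lambda_l, search, prev_tau)
  list(amplitudes = res$amplitudes, shifts = res$shifts,
       objective = sum(res$objective), per_electrode = res$objective)
}

#' Fit basis waveforms given amplitudes and shifts
#'
#' Exact solution of the waveform-update subproblem: the data term couples
#' compartments within each frequency (circular shifts are diagonal in the
#' Fourier domain), while the Gaussian shape prior couples samples within
#' each compartment, so the problem is solved as a single linear system
#' over all C*T unknowns. The normal-equation blocks for the data term are
#' circulant (block (c, d) is a weighted sum of circular-shift matrices
#' with offsets `tau_d - tau_c`), which is exploited when assembling the
#' system. With `lambda_p > 0` the system is always full rank, even when a
#' compartment has no supporting electrodes.
#'
#' @param ei an [electrical_image()]
#' @param A C x N nonnegative amplitude matrix
#' @param tau C x N integer shift matrix
#' @param prior a [build_shape_prior()]
#' @return C x T matrix of updated basis waveforms
#' @export
fit_waveforms <- function(ei, A, tau, prior) {
  X <- ei$data
  T <- nrow(X); N <- ncol(X); C <- nrow(A)
  if (prior$lambda_p == 0 && any(rowSums(A != 0) == 0)) {
    stop("rank-deficient waveform system: unobserved compartment with lambda_p = 0")
  }
  M <- matrix(0, C * T, C * T)
  rhs <- numeric(C * T)
  ij <- outer(0:(T - 1), 0:(T - 1), "-") %% T + 1L  # circulant index pattern
  for (c in seq_len(C)) {
    idx_c <- ((c - 1) * T + 1):(c * T)
    # data part of the right-hand side: sum_n A[c,n] * S_{tau}' x_n
    r <- numeric(T)
    for (n in seq_len(N)) {
      if (A[c, n] != 0) r <- r + A[c, n] * circ_shift(X[, n], -tau[c, n])
    }
    rhs[idx_c] <- r
    for (d in seq_len(C)) {
      idx_d <- ((d - 1) * T + 1):(d * T)
      w <- numeric(T)
      delta <- (tau[d, ] - tau[c, ]) %% T
      ww <- A[c, ] * A[d, ]
      for (n in seq_len(N)) {
        if (ww[n] != 0) w[delta[n] + 1L] <- w[delta[n] + 1L] + ww[n]
      }
      M[idx_c, idx_d] <- w[ij]
    }
    if (prior$lambda_p > 0) {
      M[idx_c, idx_c] <- M[idx_c, idx_c] + prior$lambda_p * prior$prec[[c]]
      rhs[idx_c] <- rhs[idx_c] + prior$lambda_p * drop(prior$prec[[c]] %*% prior$mu[c, ])
    }
  }
  Bv <- tryCatch(solve(M, rhs), error = function(e) {
    stop("singular waveform-update system: ", conditionMessage(e))
  })
  matrix(Bv, C, T, byrow = TRUE)
}

#' Full decomposition objective
#'
#' The fitted objective is the sum of three terms: a least-squares data
#' fidelity term `0.5 * sum_n ||B(tau_n) a_n - x_n||^2`, the L2,1
#' group-sparsity penalty `lambda_l * sum_n sum_g ||a_{g,n}||_2` over the
#' amplitude groups \{soma, dendrite\} and \{axon\}, and the Gaussian
#' waveform-shape prior `(lambda_p / 2) sum_c (B_c - mu_c)' K_c (B_c - mu_c)`.
#'
#' @param ei an [electrical_image()]
#' @param B,A,tau decomposition parameters (or pass a fitted
#'   `ei_decomposition` via [decomposition_objective.ei_decomposition])
#' @param prior a [build_shape_prior()]
#' @return scalar objective value
#' @export
decomposition_objective <- function(ei, B, A, tau, prior) {
  if (inherits(B, "ei_decomposition")) {
    fit <- B
    return(decomposition_objective(ei, fit$waveforms, fit$amplitudes,
                                   fit$shifts, prior))
  }
  recon <- reconstruct_matrix(B, A, tau)
  data_term <- 0.5 * sum((recon - ei$data)^2)
  groups <- c(1L, 1L, 2L)[seq_len(nrow(A))]
  pen <- sum(apply(A, 2, function(a) {
    sum(tapply(seq_along(a), groups, function(i) sqrt(sum(a[i]^2))))
  }))
  data_term + prior$lambda_l * pen + prior_penalty(B, prior)
}

reconstruct_matrix <- function(B, A, tau) {
  T <- ncol(B); N <- ncol(A)
  out <- matrix(0, T, N)
  for (n in seq_len(N)) {
    for (c in seq_len(nrow(B))) {
      if (A[c, n] != 0) out[, n] <- out[, n] + A[c, n] * circ_shift(B[c, ], tau[c, n])
    }
  }
  out
}

#' Decompose an electrical image into compartment waveforms
#'
#' Fits the shifted semi-nonnegative factorization of an EI: three basis
#' waveforms (soma, dendrite, axon) shared across electrodes, with a
#' nonnegative amplitude and an integer circular time shift per compartment
#' per electrode. The non-convex objective (see
#' [decomposition_objective()]) is minimized by alternating between (1) a
#' per-electrode amplitude and shift fitting step (coarse-to-fine shift
#' search + FISTA, basis fixed) and (2) an exact basis-waveform update
#' (linear system, amplitudes and shifts fixed). Both steps are descent
#' steps (the previous shifts are always among the search candidates), so
#' the recorded objective trace is non-increasing.
#'
#' @param ei an [electrical_image()]
#' @param prior a [build_shape_prior()]; its means also serve as the
#'   initial basis waveforms unless `init` is given
#' @param init optional C x T initial basis waveforms
#' @param search a [shift_search()] configuration
#' @param max_iters maximum alternations (default 50)
#' @param tol relative objective-decrease convergence tolerance (default 1e-6)
#' @return an object of class `ei_decomposition` with components
#'   `waveforms` (C x T), `amplitudes` (C x N), `shifts` (C x N),
#'   `objective_trace`, `converged`, `hyperparams`, and the input `ei`
#' @seealso [reconstruct_ei()], [soma_center()], [dendritic_center()]
#' @examples
#' arr <- hex_array(2, 30)
#' cell <- synthesize_cell(arr, seed = 1)
#' ei <- synthesize_cell_ei(cell, arr, noise_sd = 0.5, seed = 1)
#' prior <- build_shape_prior(cell$templates, lambda_l = default_lambda_l(ei))
#' fit <- fit_decomposition(ei, prior, max_iters = 3)
#' fit
#' @export
fit_decomposition <- function(ei, prior, init = NULL,
                              search = shift_search(), max_iters = 50L,
                              tol = 1e-6) {
  B <- if (is.null(init)) prior$mu else as.matrix(init)
  C <- nrow(B)
  trace <- numeric(0)
  A <- NULL; tau <- NULL
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    step1 <- fit_amplitudes_shifts(ei, B, prior, search, prev_tau = tau)
    if (!is.null(A)) {
      # keep the previous per-electrode solution wherever the new one is
      # not an improvement (protects monotonicity against solver tolerance)
      for (n in seq_len(ncol(A))) {
        old <- electrode_objective(ei$data[, n], B, A[, n], tau[, n],
                                   prior$lambda_l)
        if (old < step1$per_electrode[n]) {
          step1$amplitudes[, n] <- A[, n]
          step1$shifts[, n] <- tau[, n]
          step1$per_electrode[n] <- old
        }
      }
    }
    A <- step1$amplitudes; tau <- step1$shifts
    trace <- c(trace, sum(step1$per_electrode) + prior_penalty(B, prior))

    B_new <- fit_waveforms(ei, A, tau, prior)
    if (prior$lambda_p == 0) {
      # reset unobserved compartments to the prior mean to keep the
      # compartment interpretation stable
      dead <- rowSums(A != 0) == 0
      B_new[dead, ] <- prior$mu[dead, , drop = FALSE]
    }
    obj <- decomposition_objective(ei, B_new, A, tau, prior)
    if (obj <= trace[length(trace)]) B <- B_new else obj <- trace[length(trace)]
    trace <- c(trace, obj)

    m <- length(trace)
    if (m >= 3) {
      prev_full <- trace[m - 2]
      if (abs(prev_full - obj) <= tol * max(abs(prev_full), 1e-12)) {
        converged <- TRUE
        break
      }
    }
  }
  structure(
    list(waveforms = B, amplitudes = A, shifts = tau,
         objective_trace = trace, converged = converged,
         hyperparams = list(lambda_l = prior$lambda_l,
                            lambda_p = prior$lambda_p,
                            kernel_length = prior$kernel_length,
                            search = search$mode, max_iters = max_iters,
                            tol = tol),
         prior = prior, ei = ei),
    class = "ei_decomposition"
  )
}

#' Reconstruct an EI from a decomposition
#'
#' Column `n` of the reconstruction is
#' `sum_c A[c, n] * circ_shift(B_c, tau[c, n])`.
#'
#' @param fit an `ei_decomposition`
#' @return an [electrical_image()] holding the reconstruction
#' @export
reconstruct_ei <- function(fit) {
  recon <- reconstruct_matrix(fit$waveforms, fit$amplitudes, fit$shifts)
  electrical_image(recon, fit$ei$array, fit$ei$sampling_rate,
                   fit$ei$pre_samples, fit$ei$n_spikes)
}

compartment_names <- c("soma", "dendrite", "axon")

#' Canonicalize a decomposition's scale convention
#'
#' The factorization has a per-compartment scale ambiguity (`B_c -> s B_c`,
#' `A_c -> A_c / s` leaves every reconstruction unchanged; the shape prior
#' only weakly pins the scale). For cross-cell comparisons of waveform
#' shapes and amplitude norms, fits are put in the canonical convention:
#' each basis waveform is normalized to unit peak absolute amplitude and
#' the scale is folded into the amplitudes.
#'
#' @param fit an `ei_decomposition`
#' @return the fit with unit-peak waveforms and rescaled amplitudes
#' @export
canonicalize_decomposition <- function(fit) {
  s <- apply(abs(fit$waveforms), 1, max)
  s[s == 0] <- 1
  fit$waveforms <- fit$waveforms / s
  fit$amplitudes <- fit$amplitudes * s
  fit
}

#' @export
print.ei_decomposition <- function(x, ...) {
  C <- nrow(x$amplitudes)
  cat(sprintf("<ei_decomposition> %d compartments x %d electrodes, %d half-iterations\n",
              C, ncol(x$amplitudes), length(x$objective_trace)))
  cat(sprintf("  final objective %.6g (%s)\n", tail_obj(x),
              if (x$converged) "converged" else "iteration cap reached"))
  nrm <- sqrt(rowSums(x$amplitudes^2))
  cat("  amplitude L2 norms: ",
      paste(sprintf("%s=%.3g", compartment_names[seq_len(C)], nrm),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

tail_obj <- function(x) x$objective_trace[length(x$objective_trace)]

#' @export
summary.ei_decomposition <- function(object, ...) {
  res <- reconstruct_matrix(object$waveforms, object$amplitudes, object$shifts) -
    object$ei$data
  out <- list(
    n_electrodes = ncol(object$amplitudes),
    objective = tail_obj(object),
    converged = object$converged,
    amplitude_norms = stats::setNames(sqrt(rowSums(object$amplitudes^2)),
                                      compartment_names[seq_len(nrow(object$amplitudes))]),
    active_electrodes = colSums(object$amplitudes > 0),
    rel_mse = sum(res^2) / sum(object$ei$data^2),
    hyperparams = object$hyperparams
  )
  class(out) <- "summary.ei_decomposition"
  out
}

#' @export
print.summary.ei_decomposition <- function(x, ...) {
  cat(sprintf("EI decomposition over %d electrodes (%s)\n", x$n_electrodes,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  objective: %.6g\n  reconstruction MSE / signal power: %.3g\n",
              x$objective, x$rel_mse))
  cat("  compartment amplitude norms:\n")
  print(round(x$amplitude_norms, 4))
  invisible(x)
}

#' @export
coef.ei_decomposition <- function(object, ...) object$amplitudes

#' @export
fitted.ei_decomposition <- function(object, ...) {
  reconstruct_matrix(object$waveforms, object$amplitudes, object$shifts)
}

#' @export
residuals.ei_decomposition <- function(object, ...) {
  object$ei$data - fitted(object)
}

#' @export
predict.ei_decomposition <- function(object, ...) reconstruct_ei(object)

#' @export
plot.ei_decomposition <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  T <- ncol(x$waveforms)
  tt <- (seq_len(T) - 1 - x$ei$pre_samples) / x$ei$sampling_rate * 1000
  graphics::matplot(tt, t(x$waveforms), type = "l", lty = 1,
                    col = c("red", "darkgreen", "blue"),
                    xlab = "time rel. spike (ms)", ylab = "waveform (uV)",
                    main = "basis waveforms")
  graphics::legend("topright", legend = compartment_names[seq_len(nrow(x$waveforms))],
                   col = c("red", "darkgreen", "blue"), lty = 1, bty = "n")
  pos <- x$ei$array$positions
  dom <- apply(x$amplitudes, 2, which.max)
  amp <- apply(x$amplitudes, 2, max)
  graphics::plot(pos[, 1], pos[, 2], cex = 0.2 + 2.5 * amp / max(amp, 1e-12),
                 col = c("red", "darkgreen", "blue")[dom], pch = 16, asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "dominant compartment per electrode")
  invisible(x)
}

#' Write / read a fitted decomposition
#'
#' JSON text container mirroring the fit layout: `fit/waveforms` (C x T),
#' `fit/amplitudes` (C x N), `fit/shifts`, `fit/objective_trace`, and the
#' hyperparameter snapshot.
#'
#' @param fit an `ei_decomposition`
#' @param path file path
#' @export
write_fit <- function(fit, path) {
  obj <- list(format = "ei-fit-json", version = 1L,
              fit = list(waveforms = fit$waveforms,
                         amplitudes = fit$amplitudes,
                         shifts = fit$shifts,
                         objective_trace = fit$objective_trace,
                         converged = fit$converged,
                         hyperparams = fit$hyperparams))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$fit)) stop("not a decomposition-fit container")
  f <- obj$fit
  structure(list(waveforms = as.matrix(f$waveforms),
                 amplitudes = as.matrix(f$amplitudes),
                 shifts = matrix(as.integer(as.matrix(f$shifts)),
                                 nrow(as.matrix(f$shifts))),
                 objective_trace = f$objective_trace,
                 converged = isTRUE(f$converged),
                 hyperparams = as.list(f$hyperparams)),
            class = "ei_decomposition")
}

#' Hyperparameter grid sweep
#'
#' Refits the decomposition for every combination of sparsity and prior
#' weights on a (typically log-spaced) grid, recording the final objective
#' and reconstruction error for each combination. Mirrors the sensitivity
#' analysis over the two regularization weights.
#'
#' @param ei an [electrical_image()]
#' @param templates C x T prior mean waveforms
#' @param lambda_l_grid,lambda_p_grid numeric grids
#' @param ... forwarded to [fit_decomposition()]
#' @return data frame with one row per combination (`lambda_l`, `lambda_p`,
#'   `objective`, `rel_mse`, `converged`)
#' @export
sweep_hyperparams <- function(ei, templates, lambda_l_grid, lambda_p_grid, ...) {
  grid <- expand.grid(lambda_l = lambda_l_grid, lambda_p = lambda_p_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    prior <- build_shape_prior(templates, ei$sampling_rate,
                               lambda_l = grid$lambda_l[i],
                               lambda_p = grid$lambda_p[i])
    fit <- fit_decomposition(ei, prior, ...)
    s <- summary(fit)
    data.frame(lambda_l = grid$lambda_l[i], lambda_p = grid$lambda_p[i],
               objective = s$objective, rel_mse = s$rel_mse,
               converged = s$converged)
  })
  do.call(rbind, rows)
}
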