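#' Nonnegative group-lasso solver
#'
#' Solves the per-electrode amplitude subproblem
#' \deqn{\min_{a \ge 0} \tfrac12 \|D a - y\|_2^2 +
#'       \lambda \sum_g \|a_g\|_2}
#' by FISTA with constant step `1 / ||D'D||_2` and proximal operator given
#' by Euclidean projection onto the nonnegative orthant composed with
#' groupwise soft-thresholding. The L2,1 penalty groups used in the EI
#' decomposition are \{soma, dendrite\} and \{axon\}, so whole compartment
#' groups are zeroed on electrodes without signal.
#'
#' @param design T x C design matrix (shifted basis waveforms as columns)
#' @param target length-T response vector
#' @param lambda sparsity weight (>= 0)
#' @param groups integer vector of length C assigning each column to a
#'   penalty group (default `c(1, 1, 2)`: soma+dendrite, axon)
#' @param tol fixed-point tolerance on the iterate change (default 1e-10;
#'   the per-iteration change understates the distance to the optimum, so
#'   the default is set below the accuracy actually required)
#' @param maxit iteration cap (default 10000)
#' @return length-C nonnegative coefficient vector
#' @export
solve_nonneg_group_lasso <- function(design, target, lambda,
                                     groups = c(1L, 1L, 2L),
                                     tol = 1e-10, maxit = 10000L) {
  design <- as.matrix(design)
  stopifnot_finite(design, "design")
  stopifnot_finite(target, "target")
  if (lambda < 0) stop("lambda must be >= 0")
  if (length(groups) != ncol(design)) stop("groups must have one entry per column")
  g0 <- as.integer(factor(groups)) - 1L
  drop(cpp_fista_group_lasso(design, as.numeric(target), lambda, g0,
                             tol, as.integer(maxit)))
}

# objective of the per-electrode subproblem for a given (a, tau), used for
# monotonicity safeguards; groups on the amplitude vector
electrode_objective <- function(x, B, a, tau, lambda, groups = c(1L, 1L, 2L)) {
  C <- nrow(B)
  recon <- numeric(length(x))
  for (c in seq_len(C)) {
    if (a[c] != 0) recon <- recon + a[c] * circ_shift(B[c, ], tau[c])
  }
  pen <- sum(tapply(seq_len(C), groups, function(i) sqrt(sum(a[i]^2))))
  0.5 * sum((recon - x)^2) + lambda * pen
}
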