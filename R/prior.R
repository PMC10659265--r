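#' Gaussian waveform-shape prior
#'
#' Builds the Gaussian prior on compartment basis waveforms. The prior on
#' compartment c contributes `(lambda_p / 2) * (B_c - mu_c)' K_c (B_c - mu_c)`
#' to the objective, where the precision matrices `K_c` are radial basis
#' function (RBF) kernels over the sample times,
#' `K[i, j] = exp(-(t_i - t_j)^2 / (2 L^2))`, with length scale
#' `L = kernel_length` (default 250 us) and a small diagonal jitter (1e-6)
#' for positive definiteness. The prior keeps the waveform-update linear
#' system full rank even when a compartment is unobserved, and weakly
#' anchors the learned waveforms to the stereotyped compartment shapes.
#'
#' @param templates C x T matrix of prior mean waveforms `mu_c` (typically
#'   [stereotyped_templates()] or per-compartment means over a reference
#'   preparation)
#' @param sampling_rate sampling rate in Hz
#' @param kernel_length RBF length scale in seconds (default 250e-6)
#' @param lambda_l L2,1 group-sparsity weight on the amplitudes (>= 0)
#' @param lambda_p prior weight on the waveform shapes (>= 0)
#' @param jitter diagonal jitter added to each kernel matrix
#' @return an object of class `shape_prior` with fields `mu` (C x T),
#'   `prec` (list of C T x T precision matrices), `lambda_l`, `lambda_p`
#' @export
build_shape_prior <- function(templates, sampling_rate = 20000,
                              kernel_length = 250e-6, lambda_l = 0,
                              lambda_p = 1, jitter = 1e-6) {
  if (kernel_length <= 0) stop("kernel_length must be positive")
  if (lambda_l < 0 || lambda_p < 0) stop("regularization weights must be >= 0")
  templates <- as.matrix(templates)
  T <- ncol(templates)
  tt <- (seq_len(T) - 1) / sampling_rate
  K <- exp(-outer(tt, tt, "-")^2 / (2 * kernel_length^2)) + jitter * diag(T)
  prec <- rep(list(K), nrow(templates))
  structure(
    list(mu = unname(templates), prec = prec, lambda_l = lambda_l,
         lambda_p = lambda_p, kernel_length = kernel_length,
         sampling_rate = sampling_rate),
    class = "shape_prior"
  )
}

#' @export
print.shape_prior <- function(x, ...) {
  cat(sprintf(
    "<shape_prior> C=%d compartments, T=%d, kernel length %g us, lambda_l=%g, lambda_p=%g\n",
    nrow(x$mu), ncol(x$mu), x$kernel_length * 1e6, x$lambda_l, x$lambda_p))
  invisible(x)
}

# prior penalty (lambda_p / 2) sum_c d_c' K_c d_c
prior_penalty <- function(B, prior) {
  if (prior$lambda_p == 0) return(0)
  s <- 0
  for (c in seq_len(nrow(B))) {
    d <- B[c, ] - prior$mu[c, ]
    s <- s + drop(crossprod(d, prior$prec[[c]] %*% d))
  }
  prior$lambda_p / 2 * s
}

#' Default amplitude-sparsity weight for an EI
#'
#' The sparsity weight `lambda_l` is expressed relative to the signal scale:
#' by default 0.05 times the median over electrodes of the per-electrode
#' peak absolute voltage. Printed reference values for the weights are not
#' available, so this heuristic scale (together with `lambda_p = 1` in
#' units where the prior means have unit somatic peak) is exposed and can
#' be swept over a log grid with [sweep_hyperparams()].
#'
#' @param ei an [electrical_image()]
#' @param frac fraction of the median peak amplitude (default 0.05)
#' @return a scalar sparsity weight
#' @export
default_lambda_l <- function(ei, frac = 0.05) {
  frac * median(apply(abs(ei$data), 2, max))
}
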