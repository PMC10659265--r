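#' @useDynLib eidecomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median prcomp glm binomial predict coef
#' @importFrom utils head read.csv write.csv
NULL

#' Circularly shift a vector
#'
#' Shifts `v` forward in time by `s` samples with wraparound, i.e.
#' `out[t] = v[(t - s) mod T]`. This is the shift convention used throughout
#' the decomposition (integer shifts, circular / mod-T).
#'
#' @param v numeric vector
#' @param s integer shift (any sign)
#' @return shifted vector of the same length
#' @export
circ_shift <- function(v, s) {
  T <- length(v)
  s <- as.integer(s) %% T
  if (s == 0L) return(v)
  idx <- ((seq_len(T) - 1L - s) %% T) + 1L
  v[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
}
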