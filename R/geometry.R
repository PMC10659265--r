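#' Somatic center from a decomposition
#'
#' Amplitude-weighted center-of-mass over the electrode with the largest
#' somatic amplitude and its six nearest neighbors (all available nearest
#' electrodes are used near array edges).
#'
#' @param fit an `ei_decomposition` (or a 3 x N amplitude matrix)
#' @param array the [electrode_array()]; taken from the fit if omitted
#' @param k number of neighbors (default 6)
#' @return length-2 position in um
#' @export
soma_center <- function(fit, array = NULL, k = 6L) {
  A <- if (inherits(fit, "ei_decomposition")) fit$amplitudes else as.matrix(fit)
  if (is.null(array)) array <- fit$ei$array
  a <- A[1, ]
  if (all(a == 0)) stop("no somatic signal: all somatic amplitudes are zero")
  e0 <- which.max(a)
  idx <- c(e0, neighbor_indices(array, e0, min(k, array$n - 1L)))
  w <- a[idx]
  colSums(array$positions[idx, , drop = FALSE] * w) / sum(w)
}

#' Dendritic-field center from a decomposition
#'
#' Amplitude-weighted center-of-mass over the electrodes whose dendritic
#' amplitude exceeds `threshold_frac` times the maximum dendritic
#' amplitude.
#'
#' @param fit an `ei_decomposition` (or a 3 x N amplitude matrix)
#' @param array the [electrode_array()]; taken from the fit if omitted
#' @param threshold_frac fraction of the max dendritic amplitude (default 0.1)
#' @return length-2 position in um
#' @export
dendritic_center <- function(fit, array = NULL, threshold_frac = 0.1) {
  A <- if (inherits(fit, "ei_decomposition")) fit$amplitudes else as.matrix(fit)
  if (is.null(array)) array <- fit$ei$array
  a <- A[2, ]
  keep <- a > threshold_frac * max(a)
  if (!any(keep)) stop("no dendritic signal above threshold")
  w <- a[keep]
  colSums(array$positions[keep, , drop = FALSE] * w) / sum(w)
}

#' Affine transform container
#'
#' @param linear 2 x k matrix (k = 2 for planar maps, 4 when somatic and
#'   dendritic coordinates are stacked as predictors)
#' @param offset length-2 vector
#' @param inlier_mask optional logical vector from a robust fit
#' @return an `affine_transform`
#' @export
affine_transform <- function(linear, offset, inlier_mask = NULL) {
  linear <- as.matrix(linear)
  stopifnot_finite(linear, "linear part")
  stopifnot_finite(offset, "offset")
  structure(list(linear = linear, offset = as.numeric(offset),
                 inlier_mask = inlier_mask),
            class = "affine_transform")
}

#' Apply an affine transform to points
#' @param tf an [affine_transform()]
#' @param pts n x k point matrix
#' @return n x 2 matrix
#' @export
apply_affine <- function(tf, pts) {
  pts <- rbind2mat(pts, ncol(tf$linear))
  t(tf$linear %*% t(pts) + tf$offset)
}

#' Invert a planar affine transform
#' @param tf an [affine_transform()] with invertible 2 x 2 linear part
#' @return the inverse `affine_transform`
#' @export
invert_affine <- function(tf) {
  if (ncol(tf$linear) != 2L) stop("only planar (k = 2) transforms are invertible")
  Li <- solve(tf$linear)
  affine_transform(Li, -drop(Li %*% tf$offset))
}

rbind2mat <- function(pts, k) {
  pts <- if (is.null(dim(pts))) matrix(pts, ncol = k) else as.matrix(pts)
  if (ncol(pts) != k) stop(sprintf("expected %d predictor columns", k))
  pts
}

ls_affine <- function(src, dst) {
  X <- cbind(1, src)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) stop("rank-deficient predictors in affine fit")
  beta <- qr.coef(qr_, dst)  # (k+1) x 2
  affine_transform(t(beta[-1, , drop = FALSE]), beta[1, ])
}

#' Robust affine registration by RANSAC
#'
#' Fits the planar affine map `dst ~ linear %*% src + offset` robustly:
#' repeatedly fits on random minimal samples of 3 correspondences, counts
#' inliers within `inlier_tol`, and refits by least squares on the largest
#' consensus set. Robust to outliers such as correspondences distorted at
#' array boundaries. Deterministic given `seed`; with no outliers the
#' result equals the plain least-squares fit.
#'
#' @param src,dst n x 2 matrices of corresponding points (n >= 3,
#'   non-collinear)
#' @param n_iters RANSAC iterations (default 500)
#' @param inlier_tol inlier residual tolerance, same units as `dst`
#' @param seed integer seed
#' @return an [affine_transform()] with `inlier_mask`
#' @export
ransac_affine <- function(src, dst, n_iters = 500L, inlier_tol = 1,
                          seed = 0L) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 3L) stop("at least 3 correspondences are required")
  collinear <- function(p) {
    abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) < 1e-9
  }
  if (qr(cbind(1, src))$rank < 3L) stop("all correspondences are collinear")
  best_mask <- NULL; best_count <- -1L
  withr_seed(seed, {
    for (it in seq_len(n_iters)) {
      pick <- sample.int(n, 3L)
      if (collinear(src[pick, , drop = FALSE])) next
      tf <- tryCatch(ls_affine(src[pick, , drop = FALSE],
                               dst[pick, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) next
      res <- sqrt(rowSums((apply_affine(tf, src) - dst)^2))
      mask <- res <= inlier_tol
      if (sum(mask) > best_count) {
        best_count <- sum(mask); best_mask <- mask
      }
    }
  })
  if (is.null(best_mask) || best_count < 3L) {
    stop("RANSAC failed to find a consensus set")
  }
  tf <- ls_affine(src[best_mask, , drop = FALSE], dst[best_mask, , drop = FALSE])
  tf$inlier_mask <- best_mask
  tf
}

#' Receptive-field center from a spike-triggered average
#'
#' Implements center-of-mass receptive-field estimation from an STA:
#' pixels are flagged significant when their peak absolute z-score over
#' frames exceeds `significance_z`, with the noise SD estimated from the
#' frames preceding the STA peak; the RF time course is the mean time
#' series over significant pixels; a 2D intensity map is formed by
#' regressing each pixel's time series onto that time course; and the RF
#' center is the intensity-weighted centroid of the significant pixels.
#' The diameter is the equivalent-circle diameter of the half-maximum
#' significant region. Centers are reported in stimulus-pixel units with
#' pixel centers at integer + 0.5.
#'
#' @param sta X x Y x frames array
#' @param significance_z z threshold for pixel significance (default 4)
#' @return a `receptive_field_estimate`: list with `center_xy`, `diameter`,
#'   `significant_pixel_mask`, `intensity_map`, `time_course`
#' @export
sta_rf_center <- function(sta, significance_z = 4) {
  dm <- dim(sta)
  if (length(dm) != 3L) stop("sta must be an X x Y x frames array")
  nf <- dm[3]
  flat <- matrix(sta, ncol = nf)  # pixel x frame
  peak_frame <- which.max(apply(abs(flat), 2, max))
  noise_frames <- seq_len(max(1L, min(peak_frame - 5L, nf - 1L)))
  noise_sd <- sd(as.numeric(flat[, noise_frames]))
  if (!is.finite(noise_sd) || noise_sd == 0) {
    noise_sd <- max(abs(flat)) * 1e-12 + 1e-300
  }
  z <- apply(abs(flat), 1, max) / noise_sd
  sig <- z > significance_z
  if (!any(sig)) stop("no receptive field: no significant pixels")
  tc <- colMeans(flat[sig, , drop = FALSE])
  beta <- drop(flat %*% tc) / sum(tc^2)
  intensity <- matrix(beta, dm[1], dm[2])
  mask <- matrix(sig, dm[1], dm[2])
  w <- abs(intensity) * mask
  px <- (seq_len(dm[1]) - 0.5)
  py <- (seq_len(dm[2]) - 0.5)
  ctr <- c(sum(outer(px, rep(1, dm[2])) * w), sum(outer(rep(1, dm[1]), py) * w)) / sum(w)
  half <- w >= 0.5 * max(w)
  diameter <- 2 * sqrt(sum(half) / pi)
  structure(list(center_xy = ctr, diameter = diameter,
                 significant_pixel_mask = mask, intensity_map = intensity,
                 time_course = tc),
            class = "receptive_field_estimate")
}

#' Receptive-field center prediction from somatic / dendritic centers
#'
#' Fits, for one cell type within one preparation, a least-squares affine
#' map from electrical predictors to measured receptive-field centers:
#' either the somatic centers alone (`mode = "soma_only"`, 2 predictor
#' coordinates) or somatic and dendritic centers stacked
#' (`mode = "soma_plus_dendrite"`, 4 predictor coordinates). Per-cell
#' errors are Euclidean distances normalized by the mean receptive-field
#' diameter of the cells supplied. The two models are nested, so the
#' in-sample error of the richer model never exceeds that of the
#' soma-only model; the interesting quantity is how much the dendritic
#' information reduces the error, which is larger for types whose
#' dendritic fields are more offset from the soma.
#'
#' @param soma n x 2 somatic centers (um)
#' @param dend n x 2 dendritic centers (um)
#' @param rf n x 2 measured receptive-field centers (stimulus units)
#' @param diameters length-n receptive-field diameters (stimulus units),
#'   or a single mean diameter
#' @param mode `"soma_only"` or `"soma_plus_dendrite"`
#' @return list with `transform` ([affine_transform()]),
#'   `normalized_errors` (length n), `median_error`
#' @export
rf_prediction_fit <- function(soma, dend = NULL, rf, diameters,
                              mode = c("soma_only", "soma_plus_dendrite")) {
  mode <- match.arg(mode)
  soma <- as.matrix(soma); rf <- as.matrix(rf)
  n <- nrow(soma)
  need <- if (mode == "soma_only") 4L else 6L
  if (n < need) stop(sprintf("%s needs at least %d cells", mode, need))
  pred <- if (mode == "soma_only") soma else cbind(soma, as.matrix(dend))
  tf <- ls_affine(pred, rf)
  err <- sqrt(rowSums((apply_affine(tf, pred) - rf)^2)) / mean(diameters)
  list(transform = tf, normalized_errors = err, median_error = median(err))
}
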