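# Independent oracles used across the suite.

# Brute-force oracle for the nonnegative group lasso: box-constrained
# L-BFGS-B on an epsilon-smoothed group penalty with continuation and warm
# starts. Independent of the package's proximal composition; validated on
# the closed-form cases before use.
oracle_nngl <- function(D, y, lambda, groups) {
  groups <- as.integer(factor(groups))
  obj <- function(a, eps) {
    pen <- sum(tapply(seq_along(a), groups,
                      function(i) sqrt(sum(a[i]^2) + eps^2)))
    0.5 * sum((D %*% a - y)^2) + lambda * pen
  }
  grad <- function(a, eps) {
    g <- drop(crossprod(D, D %*% a - y))
    for (gidx in unique(groups)) {
      i <- which(groups == gidx)
      g[i] <- g[i] + lambda * a[i] / sqrt(sum(a[i]^2) + eps^2)
    }
    g
  }
  a <- rep(0.1, ncol(D))
  for (eps in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    o <- stats::optim(a, fn = obj, gr = grad, eps = eps, method = "L-BFGS-B",
                      lower = 0, control = list(maxit = 1000, factr = 10))
    a <- o$par
  }
  a
}

# Literal projected-subgradient descent (diminishing steps); slow and
# loose, used as a secondary sanity check on a few instances.
subgrad_nngl <- function(D, y, lambda, groups, iters = 30000) {
  groups <- as.integer(factor(groups))
  G <- crossprod(D); b <- crossprod(D, y)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  a <- rep(0, ncol(D))
  best <- a; best_obj <- Inf
  objf <- function(a) {
    pen <- sum(tapply(seq_along(a), groups, function(i) sqrt(sum(a[i]^2))))
    0.5 * sum((D %*% a - y)^2) + lambda * pen
  }
  for (k in seq_len(iters)) {
    g <- drop(G %*% a - b)
    for (gidx in unique(groups)) {
      i <- which(groups == gidx)
      n <- sqrt(sum(a[i]^2))
      if (n > 0) g[i] <- g[i] + lambda * a[i] / n
    }
    a <- pmax(0, a - (1 / (L * sqrt(k))) * g)
    o <- objf(a)
    if (o < best_obj) { best_obj <- o; best <- a }
  }
  best
}

# Time-domain oracle for the waveform update: builds explicit circular
# shift matrices and the full (C*T) x (C*T) normal equations.
shift_matrix <- function(T, s) {
  S <- matrix(0, T, T)
  S[cbind(((seq_len(T) - 1 + s) %% T) + 1, seq_len(T))] <- 1
  S
}

oracle_fit_waveforms <- function(X, A, tau, mu, prec, lambda_p) {
  T <- nrow(X); N <- ncol(X); C <- nrow(A)
  M <- matrix(0, C * T, C * T)
  r <- numeric(C * T)
  for (n in seq_len(N)) {
    Dn <- matrix(0, T, C * T)
    for (c in seq_len(C)) {
      Dn[, ((c - 1) * T + 1):(c * T)] <- A[c, n] * shift_matrix(T, tau[c, n])
    }
    M <- M + crossprod(Dn)
    r <- r + drop(crossprod(Dn, X[, n]))
  }
  for (c in seq_len(C)) {
    i <- ((c - 1) * T + 1):(c * T)
    M[i, i] <- M[i, i] + lambda_p * prec[[c]]
    r[i] <- r[i] + lambda_p * drop(prec[[c]] %*% mu[c, ])
  }
  matrix(solve(M, r), C, T, byrow = TRUE)
}

# Exhaustive pair-counting AUROC oracle (ties count 1/2).
oracle_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# small noiseless synthetic EI with known ground truth on a tiny array
tiny_recovery <- function(T = 96L, seed = 1L, noise_sd = 0) {
  arr <- hex_array(2, 30)
  cell <- synthesize_cell(arr, "ON_parasol", soma_xy = c(0, 0),
                          dend_center = c(25, 10), dendritic_radius = 50,
                          axon_angle = 0, T = T, pre = as.integer(T / 3),
                          seed = seed)
  ei <- synthesize_cell_ei(cell, arr, noise_sd = noise_sd, seed = seed + 1L)
  list(arr = arr, cell = cell, ei = ei)
}
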