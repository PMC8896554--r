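# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# truncated geometric-series expansion of the analytic map:
# sum_k (1 - eta) eta^k A^(k+1), truncated when the residual mass falls
# below `tol`
map_series_oracle <- function(A, beta, tol = 1e-12) {
  eta <- exp(-beta)
  n <- nrow(A)
  S <- matrix(0, n, n)
  P <- A
  k <- 0
  repeat {
    S <- S + (1 - eta) * eta^k * P
    k <- k + 1
    if (eta^k < tol || k > 1e5) break
    P <- P %*% A
  }
  S
}

# brute-force re-statement of the trial filter
filter_oracle <- function(tb, sd_mult = 2) {
  m <- mean(tb$rt); s <- stats::sd(tb$rt)
  keep <- logical(nrow(tb))
  for (i in seq_len(nrow(tb))) {
    keep[i] <- tb$rt[i] >= 0.050 && tb$rt[i] <= m + sd_mult * s && tb$correct[i]
  }
  tb[keep, ]
}

# direct leave-one-out cross-validated squared Euclidean distance between two
# conditions, looping over folds on the raw trial vectors
cv_dist_oracle <- function(Xa, Xb) {
  na <- ncol(Xa); nb <- ncol(Xb)
  F <- max(na, nb)
  vals <- numeric(F)
  for (f in seq_len(F)) {
    ia <- ((f - 1) %% na) + 1
    ib <- ((f - 1) %% nb) + 1
    mua <- rowMeans(Xa[, -ia, drop = FALSE])
    mub <- rowMeans(Xb[, -ib, drop = FALSE])
    vals[f] <- sum((mua - mub) * (Xa[, ia] - Xb[, ib]))
  }
  mean(vals) / nrow(Xa)
}

# Pearson correlation from the definition, over enumerated lower-triangle
# pairs
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Procrustes alignment residual (rotation/reflection + translation)
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  max(abs(Xc %*% R - Yc))
}

# closed-form two-class linear discriminant (equal priors handled via
# class counts), resubstitution loss
lda_loss_oracle <- function(coords, modules) {
  modules <- as.factor(modules)
  lev <- levels(modules)
  x1 <- coords[modules == lev[1], , drop = FALSE]
  x2 <- coords[modules == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  Sw <- (crossprod(scale(x1, scale = FALSE)) +
         crossprod(scale(x2, scale = FALSE))) / (nrow(coords) - 2)
  w <- solve(Sw, mu1 - mu2)
  thr <- sum(w * (mu1 + mu2)) / 2 - log(nrow(x1) / nrow(x2))
  pred <- ifelse(coords %*% w > thr, lev[1], lev[2])
  mean(pred != as.character(modules))
}

# small fixed-length epoch array with per-condition patterns plus noise
make_epochs <- function(patterns, n_rep, noise_sd = 0, fs = 100,
                        labels = NULL) {
  n <- nrow(patterns); L <- ncol(patterns)
  if (is.null(labels)) labels <- rep(seq_len(n), each = n_rep)
  T <- length(labels)
  data <- array(stats::rnorm(L * T, sd = noise_sd), c(1, L, T))
  for (k in seq_len(T)) data[1, , k] <- data[1, , k] + patterns[labels[k], ]
  e <- epoch_array(data, fs = fs, labels = labels,
                   rts = rep((L + 1) / fs, T))
  e$truncated <- TRUE
  e
}
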