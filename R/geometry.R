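#' Classical multidimensional scaling of a dissimilarity matrix
#'
#' Double-centers the squared distances, eigendecomposes, and projects onto
#' the top nonnegative eigenpairs scaled by the square root of their
#' eigenvalues (via [stats::cmdscale()]). Exact for genuinely Euclidean
#' inputs; otherwise negative eigenvalues are dropped. If fewer than `dims`
#' nonnegative eigenvalues exist, missing coordinates are padded with zeros
#' (with a warning).
#'
#' @param d An `rdm` with polarity dissimilarity (or a symmetric matrix of
#'   distances).
#' @param dims Embedding dimension (default 2).
#' @return A list of class `embedding`: `coords` (`n x dims`, column-centered)
#'   and `method = "classical_mds"`.
#' @export
classical_mds <- function(d, dims = 2L) {
  if (inherits(d, "rdm") &&
      identical(attr(d, "polarity"), "similarity")) {
    stop("classical MDS requires a dissimilarity matrix")
  }
  m <- unclass(d)
  stopifnot(isSymmetric(unname(m)))
  fit <- stats::cmdscale(m, k = dims, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < dims) {
    warning("fewer than ", dims, " nonnegative eigenvalues; padding with zeros")
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  structure(list(coords = unname(coords), method = "classical_mds",
                 eig = fit$eig),
            class = "embedding")
}

#' Principal-component embedding of a similarity matrix
#'
#' The latent-space estimate is a similarity (probability) matrix, not a
#' Euclidean distance matrix, so classical MDS does not apply; instead the
#' matrix rows are treated as observations, columns are centered and scaled,
#' and rows are projected onto the first principal axes. The diagonal is
#' zeroed before embedding by default: the task sequence contains no
#' self-transitions, so self-similarity carries no information about the
#' learned geometry (dissimilarity matrices already have zero diagonals).
#' Zero-variance columns are dropped with a warning.
#'
#' @param s Square numeric matrix (similarity or estimate).
#' @param dims Embedding dimension (default 2).
#' @param include_diag Keep the diagonal as a feature (default `FALSE`).
#' @return A list of class `embedding`: `coords` (`n x dims`) and
#'   `method = "pca"`.
#' @export
pca_embed <- function(s, dims = 2L, include_diag = FALSE) {
  m <- unclass(s)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!include_diag) diag(m) <- 0
  v <- apply(m, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance column(s)")
    m <- m[, v > 0, drop = FALSE]
  }
  fit <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  coords <- fit$x[, seq_len(min(dims, ncol(fit$x))), drop = FALSE]
  if (ncol(coords) < dims) {
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  structure(list(coords = unname(coords), method = "pca"),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding: %s, %d points x %d dims>\n",
              x$method, nrow(x$coords), ncol(x$coords)))
  invisible(x)
}

#' Module discriminability loss of an embedding
#'
#' Fits a two-class linear discriminant to the embedded node coordinates and
#' reports the resubstitution misclassification fraction: 0 means the best
#' linear boundary separates the modules perfectly, 0.5 is chance. With only
#' ten nodes, held-out evaluation is not supported; the loss of the fitted
#' boundary is the reported quantity. Degenerate within-class covariance is
#' handled with a small ridge (`1e-8`) closed-form discriminant.
#'
#' @param emb An `embedding` (or an `n x 2` coordinate matrix).
#' @param modules Per-node module labels (exactly two distinct values).
#' @return Misclassification fraction in `[0, 1]`.
#' @export
lda_module_loss <- function(emb, modules) {
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  modules <- as.factor(modules)
  if (nlevels(modules) != 2L) stop("exactly two module labels are required")
  fit <- tryCatch({
    l <- suppressWarnings(MASS::lda(coords, grouping = modules))
    pred <- stats::predict(l, coords)$class
    mean(pred != modules)
  }, error = function(err) NULL)
  if (!is.null(fit)) return(fit)
  # ridge-regularized closed-form discriminant for degenerate covariance
  warning("degenerate within-class covariance; using ridge discriminant")
  ridge_lda_loss(coords, modules, ridge = 1e-8)
}

# closed-form two-class linear discriminant with ridge regularization;
# classifies by the sign of w'x - c with w = S^-1 (mu1 - mu2) and the
# threshold set from class means and priors
ridge_lda_loss <- function(coords, modules, ridge = 1e-8) {
  lev <- levels(modules)
  x1 <- coords[modules == lev[1], , drop = FALSE]
  x2 <- coords[modules == lev[2], , drop = FALSE]
  mu1 <- colMeans(x1); mu2 <- colMeans(x2)
  pool <- (crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))) /
    (nrow(coords) - 2)
  S <- pool + diag(ridge, ncol(coords))
  w <- solve(S, mu1 - mu2)
  thr <- sum(w * (mu1 + mu2)) / 2 -
    log(nrow(x1) / nrow(x2))
  score <- coords %*% w
  pred <- ifelse(score > thr, lev[1], lev[2])
  if (sum(abs(mu1 - mu2)) == 0) return(0.5)  # identical classes: chance
  mean(pred != as.character(modules))
}

#' Write an embedding as CSV
#'
#' @param emb An `embedding`.
#' @param path File path.
#' @export
write_embedding_csv <- function(emb, path) {
  co <- emb$coords
  utils::write.csv(
    data.frame(node = seq_len(nrow(co)), x = co[, 1], y = co[, 2]),
    path, row.names = FALSE)
  invisible(path)
}
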