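#' Epoched multichannel recordings
#'
#' Container for trial-epoched neural data: a `channels x time x trials`
#' array with sampling rate, per-trial stimulus labels and reaction times,
#' and an alignment mode. Trials may have different useful lengths (set by
#' their reaction times); [truncate_epochs()] brings them to a common length.
#'
#' @param data Numeric array `channels x time x trials`.
#' @param fs Sampling rate in Hz.
#' @param labels Integer per-trial stimulus node (1-based).
#' @param rts Numeric per-trial reaction times in seconds.
#' @param alignment One of `"stimulus"`, `"middle"`, `"response"`.
#' @param trial Optional integer trial indices (defaults to `1:n_trials`);
#'   kept so windowed analyses survive trial rejection.
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, labels, rts,
                        alignment = c("stimulus", "middle", "response"),
                        trial = NULL) {
  alignment <- match.arg(alignment)
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3] == length(labels),
            length(rts) == length(labels))
  if (is.null(trial)) trial <- seq_along(labels)
  structure(
    list(data = data, fs = fs, labels = as.integer(labels),
         rts = as.numeric(rts), alignment = alignment,
         trial = as.integer(trial), truncated = FALSE),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array: %d channels x %d samples x %d trials, %g Hz, %s-aligned%s>\n",
              d[1], d[2], d[3], x$fs, x$alignment,
              if (x$truncated) ", fixed length" else ""))
  invisible(x)
}

#' Truncate epochs to a common length
#'
#' Brings all trials to the length of the shortest trial (in samples,
#' `floor(rt * fs)`), with a floor of 200 ms: if the shortest reaction time
#' is below 200 ms, the common length is 200 ms and shorter trials are
#' discarded. Truncation respects the alignment mode: stimulus-aligned keeps
#' the first `L` samples (the evoked response), response-aligned the last `L`
#' samples before the response, and middle-aligned drops the centre of the
#' trial, keeping the first `ceiling(L/2)` and last `floor(L/2)` samples.
#'
#' @param e An `epoch_array`.
#' @param alignment Optional override of the stored alignment mode.
#' @param min_rt Floor on the common window, seconds (default 0.200).
#' @return A truncated `epoch_array` with a fixed time length.
#' @export
truncate_epochs <- function(e, alignment = NULL, min_rt = 0.200) {
  stopifnot(inherits(e, "epoch_array"))
  if (is.null(alignment)) alignment <- e$alignment
  alignment <- match.arg(alignment, c("stimulus", "middle", "response"))
  valid <- pmin(floor(e$rts * e$fs), dim(e$data)[2])
  L <- max(min(valid), ceiling(min_rt * e$fs))
  keep <- which(valid >= L)
  if (length(keep) == 0L) stop("all trials are shorter than the common length")
  d <- dim(e$data)
  out <- array(NA_real_, c(d[1], L, length(keep)))
  h1 <- ceiling(L / 2); h2 <- L - h1
  for (k in seq_along(keep)) {
    tr <- keep[k]; v <- valid[tr]
    idx <- switch(alignment,
      stimulus = seq_len(L),
      response = (v - L + 1L):v,
      middle   = c(seq_len(h1), (v - h2 + 1L):v)
    )
    out[, , k] <- e$data[, idx, tr]
  }
  structure(
    list(data = out, fs = e$fs, labels = e$labels[keep], rts = e$rts[keep],
         alignment = alignment, trial = e$trial[keep], truncated = TRUE),
    class = "epoch_array"
  )
}

#' Dissimilarity / similarity matrices
#'
#' Thin wrapper marking a square condition-pair matrix with its polarity.
#' Cross-validated dissimilarities are unbiased and may be negative.
#'
#' @param values Square numeric matrix.
#' @param polarity `"dissimilarity"` or `"similarity"`.
#' @return The matrix with class `rdm` and a `polarity` attribute.
#' @export
as_rdm <- function(values, polarity = c("dissimilarity", "similarity")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(values, class = "rdm", polarity = polarity)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm: %d x %d, %s>\n", nrow(x), ncol(x), attr(x, "polarity")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Latent-space and exact templates for similarity analysis
#'
#' `latent_template()` returns the (symmetrized) analytic latent-space
#' estimate at a given discount rate as a similarity template;
#' `exact_template()` returns the true transition matrix.
#'
#' @param g A `graph_spec`.
#' @param beta Positive discount rate.
#' @return An `rdm` with polarity `"similarity"`.
#' @export
latent_template <- function(g, beta) {
  Ahat <- map_analytic(transition_matrix(g), beta)
  as_rdm((unclass(Ahat) + t(unclass(Ahat))) / 2, "similarity")
}

#' @rdname latent_template
#' @export
exact_template <- function(g) {
  as_rdm(transition_matrix(g), "similarity")
}

#' Visual-space template from screen geometry
#'
#' Pairwise Euclidean distances between the screen positions of each node's
#' highlighted square, mapped through the stimulus-to-node assignment. The
#' default geometry is a row of ten unit-spaced squares.
#'
#' @param positions `n x 2` (or `n x 1`) matrix of screen coordinates per
#'   stimulus position; default a unit-spaced collinear row.
#' @param assignment Integer permutation mapping node index to stimulus
#'   position (default identity).
#' @param n_nodes Number of nodes (default 10).
#' @return An `rdm` with polarity `"dissimilarity"`.
#' @export
visual_template <- function(positions = NULL, assignment = NULL, n_nodes = 10L) {
  if (is.null(positions)) positions <- cbind(seq_len(n_nodes) - 1, 0)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(assignment)) assignment <- seq_len(n)
  p <- positions[assignment, , drop = FALSE]
  D <- as.matrix(stats::dist(p))
  dimnames(D) <- NULL
  as_rdm(D, "dissimilarity")
}

# --- cross-validated Euclidean distance ------------------------------------

# flatten selected channels of a truncated epoch array into an
# (channels*time) x trials matrix
epoch_matrix <- function(e, channels = NULL) {
  d <- dim(e$data)
  if (is.null(channels)) channels <- seq_len(d[1])
  x <- e$data[channels, , , drop = FALSE]
  matrix(x, nrow = length(channels) * d[2], ncol = d[3])
}

# Core estimator operating on the Gram matrix of trial vectors.
# G:      trials x trials inner-product matrix (original trial order)
# labels: per label-position condition assignments
# p:      permutation; data trial used at label position k is column p[k]
# veclen: length of the underlying trial vectors (for per-sample scaling)
rdm_from_gram <- function(G, labels, p = seq_along(labels), veclen,
                          n_nodes = max(labels)) {
  T <- length(labels)
  ip <- integer(T); ip[p] <- seq_len(T)
  g <- factor(labels[ip], levels = seq_len(n_nodes))
  counts <- tabulate(labels, nbins = n_nodes)
  if (any(counts < 2L)) {
    stop("every condition needs at least 2 trials for cross-validation")
  }
  M <- rowsum(G, g)                       # n_nodes x T condition sums
  dG <- diag(G)
  cond <- split(p, factor(labels, levels = seq_len(n_nodes)))
  D <- matrix(0, n_nodes, n_nodes)
  for (a in seq_len(n_nodes - 1L)) {
    Ia <- cond[[a]]; na <- length(Ia)
    for (b in (a + 1L):n_nodes) {
      Ib <- cond[[b]]; nb <- length(Ib)
      F <- max(na, nb)
      i <- Ia[((seq_len(F) - 1L) %% na) + 1L]
      j <- Ib[((seq_len(F) - 1L) %% nb) + 1L]
      gij <- G[cbind(i, j)]
      d2 <- ((M[a, i] - dG[i]) - (M[a, j] - gij)) / (na - 1) -
            ((M[b, i] - gij) - (M[b, j] - dG[j])) / (nb - 1)
      D[a, b] <- D[b, a] <- mean(d2) / veclen
    }
  }
  as_rdm(D, "dissimilarity")
}

#' Cross-validated Euclidean dissimilarity matrix
#'
#' Leave-one-trial-out cross-validated squared Euclidean distance between the
#' activity patterns evoked by each stimulus. Trials are vectorized over
#' (channels and) time; for each condition pair, held-out trials are paired
#' across conditions by fold index (the condition with fewer trials cycles),
#' and each fold contributes the inner product between the train-mean
#' difference and the held-out-trial difference. Cross-validation makes the
#' estimator unbiased: identical condition means give expected distance zero,
#' so entries can be negative. Values are normalized by vector length
#' (per-sample scale).
#'
#' @param e A truncated `epoch_array` (see [truncate_epochs()]).
#' @param channels Channels to include (default all, concatenated).
#' @param n_nodes Number of conditions (default `max(labels)`).
#' @return An `rdm` (symmetric, zero diagonal, polarity dissimilarity).
#' @export
cv_euclidean_rdm <- function(e, channels = NULL, n_nodes = max(e$labels)) {
  stopifnot(inherits(e, "epoch_array"))
  if (!e$truncated) stop("epochs must be truncated to a fixed length first")
  X <- epoch_matrix(e, channels)
  G <- crossprod(X)
  rdm_from_gram(G, e$labels, veclen = nrow(X), n_nodes = n_nodes)
}

#' Correlate a neural dissimilarity matrix with a template
#'
#' Pearson correlation over the 45 strictly-lower-triangle condition pairs.
#' When the template carries similarity polarity (e.g. the latent-space
#' estimate), the correlation is negated so that positive values always mean
#' "geometry matches the template".
#'
#' @param d An `rdm` with polarity dissimilarity.
#' @param template An `rdm` (either polarity).
#' @return A single correlation value.
#' @export
template_corr <- function(d, template) {
  stopifnot(nrow(d) == nrow(template))
  lt <- lower.tri(d)
  dv <- unclass(d)[lt]
  tv <- unclass(template)[lt]
  if (stats::sd(dv) == 0 || stats::sd(tv) == 0) {
    stop("undefined correlation: zero variance in lower-triangle values")
  }
  r <- stats::cor(dv, tv)
  if (identical(attr(template, "polarity"), "similarity")) -r else r
}

#' Circular-shift permutation null for template correlations
#'
#' Builds a null distribution of template correlations by rotating the trial
#' order of the neural data at a random split point while keeping the
#' stimulus labels in their original order: for a draw `s`, the data become
#' trials `(s+1, ..., T, 1, ..., s)` matched against labels `1..T`. This
#' preserves the autocorrelation structure of the recording, unlike trial
#' shuffling. Splits are drawn uniformly from `1..T-1`, so every null
#' reordering differs from the observed one.
#'
#' @param e A truncated `epoch_array`.
#' @param template Template `rdm` to correlate against.
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed.
#' @param channels Channels to include (default all, concatenated).
#' @param n_nodes Number of conditions.
#' @return An object of class `null_distribution`: list with `correlations`
#'   (length `n_perm`), `splits`, and `seed`.
#' @export
circular_shift_null <- function(e, template, n_perm = 100L, seed = NULL,
                                channels = NULL, n_nodes = max(e$labels)) {
  stopifnot(inherits(e, "epoch_array"), e$truncated)
  if (!is.null(seed)) set.seed(seed)
  X <- epoch_matrix(e, channels)
  G <- crossprod(X)
  T <- length(e$labels)
  splits <- sample.int(T - 1L, n_perm, replace = TRUE)
  cors <- vapply(splits, function(s) {
    p <- c((s + 1L):T, 1:s)
    d <- rdm_from_gram(G, e$labels, p = p, veclen = nrow(X), n_nodes = n_nodes)
    template_corr(d, template)
  }, numeric(1))
  structure(list(correlations = cors, splits = splits, seed = seed),
            class = "null_distribution")
}

#' Select contacts whose geometry matches the latent space
#'
#' A channel is selected for the latent space when (1) its latent-template
#' correlation exceeds at least `min_exceed` of the null correlations, and
#' (2) it exceeds the correlation with the exact latent space (the true
#' transition matrix). Visual-space selection applies criterion (1) only.
#'
#' @param r_latent,r_exact Per-channel template correlations.
#' @param nulls_latent Null correlations: matrix `n_perm x n_channels` or a
#'   list of `null_distribution` objects / numeric vectors.
#' @param r_visual,nulls_visual Optional visual-template correlations and
#'   nulls.
#' @param min_exceed Minimum number of null values the observed correlation
#'   must exceed; default `ceiling(0.95 * n_perm)` (95 of 100).
#' @return A data.frame with one row per channel: correlations,
#'   `null_exceed_count`, and logical `selected_latent` / `selected_visual`.
#' @export
select_contacts <- function(r_latent, r_exact, nulls_latent,
                            r_visual = NULL, nulls_visual = NULL,
                            min_exceed = NULL) {
  null_mat <- function(nulls, nch) {
    if (is.list(nulls)) {
      nulls <- vapply(nulls, function(z) {
        if (inherits(z, "null_distribution")) z$correlations else as.numeric(z)
      }, numeric(length(if (inherits(nulls[[1]], "null_distribution"))
        nulls[[1]]$correlations else nulls[[1]])))
    }
    nulls <- as.matrix(nulls)
    stopifnot(ncol(nulls) == nch)
    nulls
  }
  nch <- length(r_latent)
  NL <- null_mat(nulls_latent, nch)
  n_perm <- nrow(NL)
  if (is.null(min_exceed)) min_exceed <- ceiling(0.95 * n_perm)
  exceed <- colSums(NL < rep(r_latent, each = n_perm))
  out <- data.frame(
    channel = seq_len(nch),
    r_latent = r_latent,
    r_exact = r_exact,
    null_exceed_count = exceed,
    selected_latent = exceed >= min_exceed & r_latent > r_exact
  )
  if (!is.null(r_visual)) {
    NV <- null_mat(nulls_visual, nch)
    ev <- colSums(NV < rep(r_visual, each = nrow(NV)))
    out$r_visual <- r_visual
    out$null_exceed_visual <- ev
    out$selected_visual <- ev >= min_exceed
  }
  out
}

#' Per-channel similarity analysis with null calibration
#'
#' Runs the full channel-selection analysis: per channel, the
#' cross-validated dissimilarity matrix, its correlations with the latent,
#' exact, and (optionally) visual templates, circular-shift null
#' distributions, and the selection flags of [select_contacts()]. The Gram
#' matrix of each channel is computed once and reused across permutations.
#'
#' @param e A truncated `epoch_array`.
#' @param latent Latent-space template (`rdm`, similarity polarity).
#' @param exact Exact-space template (`rdm`, similarity polarity).
#' @param visual Optional visual template (`rdm`, dissimilarity polarity).
#' @param n_perm Number of null permutations per channel (default 100).
#' @param seed Optional integer seed.
#' @return The [select_contacts()] data.frame, with the per-channel `rdm`s
#'   attached as attribute `"rdms"`.
#' @export
rsa_select <- function(e, latent, exact, visual = NULL, n_perm = 100L,
                       seed = NULL) {
  stopifnot(inherits(e, "epoch_array"), e$truncated)
  if (!is.null(seed)) set.seed(seed)
  nch <- dim(e$data)[1]
  T <- length(e$labels)
  n_nodes <- nrow(latent)
  Ti <- dim(e$data)[2]
  r_latent <- r_exact <- r_visual <- numeric(nch)
  NL <- matrix(NA_real_, n_perm, nch)
  NV <- if (!is.null(visual)) matrix(NA_real_, n_perm, nch) else NULL
  rdms <- vector("list", nch)
  for (ch in seq_len(nch)) {
    X <- matrix(e$data[ch, , ], nrow = Ti, ncol = T)
    G <- crossprod(X)
    d <- rdm_from_gram(G, e$labels, veclen = Ti, n_nodes = n_nodes)
    rdms[[ch]] <- d
    r_latent[ch] <- template_corr(d, latent)
    r_exact[ch] <- template_corr(d, exact)
    if (!is.null(visual)) r_visual[ch] <- template_corr(d, visual)
    splits <- sample.int(T - 1L, n_perm, replace = TRUE)
    for (k in seq_len(n_perm)) {
      p <- c((splits[k] + 1L):T, 1:splits[k])
      dn <- rdm_from_gram(G, e$labels, p = p, veclen = Ti, n_nodes = n_nodes)
      NL[k, ch] <- template_corr(dn, latent)
      if (!is.null(visual)) NV[k, ch] <- template_corr(dn, visual)
    }
  }
  out <- select_contacts(r_latent, r_exact, NL,
                         r_visual = if (!is.null(visual)) r_visual,
                         nulls_visual = NV)
  attr(out, "rdms") <- rdms
  out
}
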