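#' Sliding trial windows
#'
#' Fixed-width windows over the trial axis: starts at `1, 1+step, ...` while
#' the window fits inside `1..n_trials`. The canonical design (1000 trials,
#' width 500, step 100) gives 6 windows.
#'
#' @param n_trials Total number of trials.
#' @param width Window width in trials (default 500).
#' @param step Window offset in trials (default 100).
#' @return A list of class `window_spec`: `n_trials`, `width`, `step`,
#'   `starts`.
#' @export
sliding_windows <- function(n_trials, width = 500L, step = 100L) {
  if (width > n_trials) stop("window width exceeds the number of trials")
  starts <- seq.int(1L, n_trials - width + 1L, by = step)
  structure(list(n_trials = as.integer(n_trials), width = as.integer(width),
                 step = as.integer(step), starts = as.integer(starts)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec: %d windows of %d trials, step %d, over %d trials>\n",
              length(x$starts), x$width, x$step, x$n_trials))
  invisible(x)
}

#' Sliding-window template correlations
#'
#' Recomputes the cross-validated dissimilarity matrix and its template
#' correlations within each sliding block of trials, per channel. To capture
#' convergence dynamics rather than differences in final values, each
#' window's correlation is also normalized by the full-data correlation for
#' that channel and template. Windows in which some condition has fewer than
#' two trials are reported as missing with a warning.
#'
#' @param e A truncated `epoch_array` (its `trial` indices place trials in
#'   windows).
#' @param templates Named list of template `rdm`s (e.g.
#'   `list(latent = ..., visual = ...)`).
#' @param w A `window_spec`.
#' @param channels Channels to analyse (default all).
#' @return A long data.frame: `window`, `start`, `channel`, `template`, `r`,
#'   `r_normalized`.
#' @export
windowed_template_corr <- function(e, templates, w, channels = NULL) {
  stopifnot(inherits(e, "epoch_array"), e$truncated,
            inherits(w, "window_spec"))
  if (is.null(channels)) channels <- seq_len(dim(e$data)[1])
  if (is.null(names(templates))) {
    names(templates) <- paste0("template", seq_along(templates))
  }
  n_nodes <- nrow(templates[[1]])
  Ti <- dim(e$data)[2]
  full_r <- matrix(NA_real_, length(channels), length(templates))
  grams <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    X <- matrix(e$data[channels[ci], , ], nrow = Ti)
    grams[[ci]] <- crossprod(X)
    d <- rdm_from_gram(grams[[ci]], e$labels, veclen = Ti, n_nodes = n_nodes)
    full_r[ci, ] <- vapply(templates, function(tp) template_corr(d, tp),
                           numeric(1))
  }
  rows <- list()
  for (wi in seq_along(w$starts)) {
    s <- w$starts[wi]
    sel <- which(e$trial >= s & e$trial <= s + w$width - 1L)
    counts <- tabulate(e$labels[sel], nbins = n_nodes)
    feasible <- length(sel) > 0L && all(counts >= 2L)
    if (!feasible) {
      warning(sprintf("window %d: some condition has < 2 trials; values missing", wi))
    }
    for (ci in seq_along(channels)) {
      if (feasible) {
        G <- grams[[ci]][sel, sel, drop = FALSE]
        d <- rdm_from_gram(G, e$labels[sel], veclen = Ti, n_nodes = n_nodes)
        r <- vapply(templates, function(tp) template_corr(d, tp), numeric(1))
      } else {
        r <- rep(NA_real_, length(templates))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window = wi, start = s, channel = channels[ci],
        template = names(templates), r = unname(r),
        r_normalized = unname(r) / full_r[ci, ]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window discount-rate refits
#'
#' Refits the temporal-discounting model independently inside each window.
#' Each window is treated as its own sequence: discounted counts restart at
#' the window start, and residuals are re-estimated within the window when a
#' behaviour table is supplied. Extreme fits (`beta` of 0 or infinity) are
#' reported as missing numeric values, mirroring their exclusion from
#' parametric statistics.
#'
#' @param x Integer node sequence (full walk).
#' @param behavior Either a residual data.frame (`trial`, `residual`) used
#'   as-is per window, or a filtered behaviour table, in which case
#'   [residualize_rt()] is applied within each window.
#' @param w A `window_spec`.
#' @param ... Passed to [fit_beta()].
#' @return A data.frame: `window`, `start`, `beta` (`NA` when extreme),
#'   `status`, `r0`, `r1`, `objective`.
#' @export
windowed_beta <- function(x, behavior, w, ...) {
  stopifnot(inherits(w, "window_spec"))
  is_resid <- is.data.frame(behavior) && "residual" %in% names(behavior)
  out <- lapply(seq_along(w$starts), function(wi) {
    s <- w$starts[wi]
    idx <- s:(s + w$width - 1L)
    xw <- x[idx]
    if (is_resid) {
      rw <- behavior[behavior$trial %in% idx, , drop = FALSE]
    } else {
      tb <- behavior[behavior$trial %in% idx, , drop = FALSE]
      rw <- residualize_rt(tb)
    }
    rw$trial <- rw$trial - s + 1L   # window-local trial index
    fit <- tryCatch(fit_beta(xw, rw, ...), error = function(err) NULL)
    if (is.null(fit)) {
      data.frame(window = wi, start = s, beta = NA_real_, status = "error",
                 r0 = NA_real_, r1 = NA_real_, objective = NA_real_)
    } else {
      data.frame(window = wi, start = s,
                 beta = if (fit$status == "interior") fit$beta else NA_real_,
                 status = fit$status, r0 = fit$r0, r1 = fit$r1,
                 objective = fit$objective)
    }
  })
  do.call(rbind, out)
}

#' Convergence of the finite-time estimate toward the analytic map
#'
#' Simulates random walks on a graph and tracks, at every trial `t`, the
#' Pearson correlation between the strictly-lower triangles of the
#' finite-time estimate and the analytic (infinite-time) map at the same
#' discount rate. Larger discount rates converge faster. Correlations are
#' undefined before trial 3 and reported as missing.
#'
#' @param g A `graph_spec`.
#' @param beta Positive discount rate.
#' @param n_trials Walk length (default 1000).
#' @param n_walks Number of walks to average over (default 20).
#' @param seed Optional integer seed.
#' @return A data.frame `trial`, `correlation` (mean over walks).
#' @export
convergence_curve <- function(g, beta, n_trials = 1000L, n_walks = 20L,
                              seed = NULL) {
  stopifnot(inherits(g, "graph_spec"), beta > 0)
  if (!is.null(seed)) set.seed(seed)
  A <- transition_matrix(g)
  n <- nrow(A)
  target <- map_analytic(A, beta)
  tv <- unclass(target)[lower.tri(target)]
  acc <- matrix(NA_real_, n_trials, n_walks)
  for (wk in seq_len(n_walks)) {
    x <- random_walk(A, n_trials)
    acc[, wk] <- convergence_cpp(as.integer(x), beta, n, tv)
  }
  data.frame(trial = seq_len(n_trials), correlation = rowMeans(acc))
}
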