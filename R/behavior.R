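#' Filter behavioural trials
#'
#' Removes trials that are too fast to reflect stimulus processing, unusually
#' slow for the participant, or incorrect. A trial is retained iff its
#' reaction time is at least `min_rt` seconds, no more than `sd_mult`
#' standard deviations above the participant's mean reaction time, and the
#' response was correct. The mean and standard deviation are computed once on
#' the full input table, before any exclusion, so the rule does not depend on
#' iteration order.
#'
#' @param t A behaviour table: a data.frame with at least columns
#'   `trial`, `node`, `rt` (seconds), `correct` (logical).
#' @param sd_mult Multiplier for the upper reaction-time cut (default 2).
#' @param min_rt Lower reaction-time cut in seconds (default 0.050).
#' @return The filtered data.frame (rows retained in original order).
#' @export
filter_trials <- function(t, sd_mult = 2, min_rt = 0.050) {
  if (!is.data.frame(t) || nrow(t) == 0L) stop("behaviour table is empty")
  stopifnot(all(c("rt", "correct") %in% names(t)))
  m <- mean(t$rt)
  s <- stats::sd(t$rt)
  if (is.na(s)) s <- 0
  keep <- t$rt >= min_rt & t$rt <= m + sd_mult * s & as.logical(t$correct)
  t[keep, , drop = FALSE]
}

#' Recency covariate for a stimulus sequence
#'
#' For each trial, the number of trials since the current stimulus was last
#' seen, capped at `cap`, log-transformed. Recently repeated stimuli are
#' responded to faster; this covariate absorbs that nuisance effect. A first
#' occurrence is treated as maximally non-recent (gap = `cap`).
#'
#' @param x Integer node sequence.
#' @param cap Maximum gap before saturation (default 10).
#' @return Numeric vector `log(min(gap, cap))`, same length as `x`.
#' @export
recency_covariate <- function(x, cap = 10L) {
  n <- length(x)
  if (n == 0L) stop("sequence is empty")
  last_seen <- rep(NA_integer_, max(x))
  gap <- integer(n)
  for (t in seq_len(n)) {
    ls <- last_seen[x[t]]
    gap[t] <- if (is.na(ls)) cap else min(t - ls, cap)
    last_seen[x[t]] <- t
  }
  log(gap)
}

#' Residualize reaction times on nuisance covariates
#'
#' Ordinary least-squares regression of reaction time on task covariates
#' (trial index, stage, finger, hand transition, recency, ...), returning the
#' residual series that the temporal-discounting model consumes. For a single
#' participant the multi-subject random-slope formulation collapses to OLS.
#' For multi-subject tables, pass externally computed residuals instead.
#'
#' Covariates named in `covariates` but absent from the table are skipped.
#' Collinear columns are dropped by the QR decomposition inside [stats::lm()]
#' (a warning is issued when coefficients are aliased).
#'
#' @param t A filtered behaviour table with an `rt` column.
#' @param covariates Character vector of covariate column names.
#' @return A data.frame with columns `trial` and `residual` (seconds),
#'   aligned to the retained trials.
#' @export
residualize_rt <- function(t,
                           covariates = c("trial", "stage", "finger",
                                          "hand_transition", "recency")) {
  stopifnot(is.data.frame(t), "rt" %in% names(t))
  use <- intersect(covariates, names(t))
  dat <- t
  # categorical task covariates enter as factors
  for (v in intersect(use, c("stage", "finger", "hand", "hand_transition"))) {
    dat[[v]] <- factor(dat[[v]])
    if (nlevels(dat[[v]]) < 2L) use <- setdiff(use, v)
  }
  if (length(use) == 0L) {
    res <- dat$rt - mean(dat$rt)
  } else {
    f <- stats::as.formula(paste("rt ~", paste(use, collapse = " + ")))
    fit <- stats::lm(f, data = dat)
    if (anyNA(stats::coef(fit))) {
      warning("collinear covariates dropped from the residualization design")
    }
    res <- stats::residuals(fit)
  }
  trial <- if ("trial" %in% names(dat)) dat$trial else seq_len(nrow(dat))
  data.frame(trial = trial, residual = as.numeric(res))
}
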