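#' Analytic (infinite-time) latent-space estimate
#'
#' Closed form of the temporally discounted transition-probability estimate a
#' learner converges to after an infinitely long random walk:
#' \deqn{\hat A = (1 - e^{-\beta}) A (I - e^{-\beta} A)^{-1}}
#' where `A` is the true transition matrix and `beta` the discount rate.
#' Large `beta` recovers `A` itself; as `beta` approaches 0 every transition
#' is estimated as equally likely (all entries 1/n).
#'
#' @param A Row-stochastic transition matrix.
#' @param beta Positive discount rate.
#' @return A row-stochastic matrix of the same dimension, with attributes
#'   `mode = "infinite_time"` and `beta`.
#' @export
map_analytic <- function(A, beta) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), beta > 0)
  stopifnot(all(abs(rowSums(A) - 1) < 1e-8))
  eta <- exp(-beta)
  n <- nrow(A)
  M <- diag(n) - eta * A
  # I - eta*A is strictly diagonally dominant for eta < 1, hence invertible
  Ahat <- (1 - eta) * (A %*% solve(M))
  structure(Ahat, mode_cogmap = "infinite_time", beta = beta)
}

#' Discounted transition-count update
#'
#' Adds one observed transition to the learner's discounted count matrix.
#' With history `x_1..x_t` and incoming stimulus `next_node`, every past
#' position contributes mass to the pair (its node, `next_node`) with weight
#' proportional to `exp(-beta * dt)`, `dt` the age of the position. Weights
#' are normalized by the finite geometric sum `Z` so each observed transition
#' deposits unit mass in total; in the `beta -> Inf` limit the update reduces
#' to exact counting of the most recent transition.
#'
#' @param counts `n x n` nonnegative count matrix (`n_tilde`).
#' @param history Integer node sequence observed so far (`x_1..x_t`).
#' @param next_node The incoming node (`x_{t+1}`).
#' @param beta Nonnegative discount rate (`beta = 0` weights all history
#'   uniformly).
#' @return The updated count matrix.
#' @export
update_counts <- function(counts, history, next_node, beta) {
  t <- length(history)
  if (t < 1L) stop("history is empty")
  n <- nrow(counts)
  if (next_node < 1L || next_node > n) stop("next_node out of range")
  dt <- 0:(t - 1L)
  w <- exp(-beta * dt)
  w <- w / sum(w)
  src <- history[t - dt]
  inc <- vapply(seq_len(n), function(a) sum(w[src == a]), numeric(1))
  counts[, next_node] <- counts[, next_node] + inc
  counts
}

#' Finite-time latent-space estimate from discounted counts
#'
#' Row-normalizes the discounted count matrix into transition-probability
#' estimates \eqn{\hat A_{ij}(t) = \tilde n_{ij} / \sum_k \tilde n_{ik}}.
#' Rows with no observed mass are set to the uniform distribution `1/n`, so
#' the estimate (and hence anticipation) is defined from the second trial on.
#'
#' @param counts `n x n` nonnegative count matrix.
#' @return A row-stochastic matrix with attribute `mode = "finite_time"`.
#' @export
map_from_counts <- function(counts) {
  n <- nrow(counts)
  rs <- rowSums(counts)
  Ahat <- counts / ifelse(rs > 0, rs, 1)
  Ahat[rs == 0, ] <- 1 / n
  structure(Ahat, mode_cogmap = "finite_time")
}

#' Anticipation series of a discounted-count learner
#'
#' Runs the discounted-count learner along a node sequence and returns, for
#' each trial `t >= 2`, the probability the learner assigned at trial `t - 1`
#' to the transition it then actually observed:
#' \eqn{a(t) = \hat A_{x_{t-1}, x_t}(t-1)}. Values lie in `[0, 1]`; the first
#' trial has no prediction and is returned as `NA`.
#'
#' The sequential count updates are evaluated with an `O(n)` per-trial
#' recursion (exponential decay of per-node history weights), which is exactly
#' equivalent to accumulating [update_counts()] trial by trial.
#'
#' @param x Integer node sequence (length at least 2).
#' @param beta Nonnegative discount rate.
#' @param n_nodes Number of nodes (defaults to `max(x)`).
#' @return Numeric vector `a` with `a[1] = NA` and `a[t]` as above.
#' @export
anticipation <- function(x, beta, n_nodes = max(x)) {
  T <- length(x)
  if (T < 2L) stop("sequence must have length at least 2")
  anticipation_cpp(as.integer(x), beta, as.integer(n_nodes))
}

# run the discounted-count learner over a full sequence, returning the final
# count matrix (internal; shared with the dynamics module)
run_counts <- function(x, beta, n_nodes = max(x)) {
  run_counts_cpp(as.integer(x), beta, as.integer(n_nodes))
}

#' Linear reaction-time read-out of anticipation
#'
#' Least-squares fit of the linear prediction `r(t) = r0 + r1 * a(t)`:
#' the intercept `r0` is the reaction time with zero anticipation and the
#' slope `r1` (expected negative) the strength with which reaction times
#' track internal expectations.
#'
#' @param a Anticipation series (values in `[0, 1]`; `NA`s dropped pairwise).
#' @param resid Reaction-time residuals aligned with `a`.
#' @return List with `r0`, `r1`, and `objective` (root-mean-square error of
#'   the fit, seconds).
#' @export
fit_rt_linear <- function(a, resid) {
  ok <- !is.na(a) & !is.na(resid)
  a <- a[ok]; r <- resid[ok]
  if (length(a) < 3L) stop("need at least 3 aligned trials")
  if (stats::sd(a) == 0) {
    warning("anticipation is constant; slope set to 0")
    r0 <- mean(r); r1 <- 0
  } else {
    cf <- stats::lm.fit(cbind(1, a), r)$coefficients
    r0 <- cf[[1]]; r1 <- cf[[2]]
  }
  pred <- r0 + r1 * a
  list(r0 = r0, r1 = r1, objective = sqrt(mean((r - pred)^2)))
}

#' Logarithmic search grid for the discount rate
#'
#' @param n Number of grid points (default 100).
#' @param lower,upper Grid range (defaults `1e-4` and `10`).
#' @return Numeric vector of `n` logarithmically spaced values.
#' @export
beta_grid <- function(n = 100L, lower = 1e-4, upper = 10) {
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Fit the temporal-discounting model to reaction-time residuals
#'
#' The core estimator. For a candidate discount rate `beta`, the discounted
#' count learner is run along the stimulus sequence to produce the
#' anticipation series `a(t)`, and the linear read-out `r0 + r1 * a(t)` is
#' fit to the residual reaction times by least squares; the objective is the
#' root-mean-square prediction error. The objective is evaluated on a
#' 100-point logarithmic grid over `[1e-4, 10]`, and gradient descent (central
#' finite differences in `log(beta)` with a backtracking line search) then
#' refines the grid minimum until the absolute gradient falls below `1e-6`.
#' The search terminates with an extreme status if `beta` collapses to 0 or
#' grows beyond 1000; extreme fits are flagged and should be excluded from
#' parametric statistics on `beta`.
#'
#' @param x Integer node sequence (the full stimulus walk).
#' @param resid Residual series: a data.frame with columns `trial` and
#'   `residual` (as from [residualize_rt()]), or a numeric vector aligned
#'   with `x`.
#' @param n_nodes Number of nodes (defaults to `max(x)`).
#' @param grid Candidate grid (default [beta_grid()]).
#' @param min_trials Minimum number of usable trials (default 50).
#' @param grad_tol Gradient convergence tolerance (default `1e-6`).
#' @param max_iter Maximum descent iterations (default 500).
#' @return An object of class `beta_fit` with elements `beta`, `r0`, `r1`,
#'   `objective` (RMSE, seconds), `status` (`"interior"`, `"zero"`, or
#'   `"infinite"`), `grid` (data.frame of grid betas and objectives),
#'   `anticipation` (series at the fitted beta), `trials` (usable trial
#'   indices), `resid` (their residuals), and `n`.
#' @seealso [map_analytic()], [anticipation()]
#' @examples
#' g <- build_modular_graph()
#' x <- random_walk(transition_matrix(g), 300, seed = 1)
#' a <- anticipation(x, beta = 0.5)
#' resid <- -0.3 * a + stats::rnorm(300, sd = 0.02)
#' fit <- fit_beta(x, resid)
#' coef(fit)
#' @export
fit_beta <- function(x, resid, n_nodes = max(x), grid = beta_grid(),
                     min_trials = 50L, grad_tol = 1e-6, max_iter = 500L) {
  if (is.data.frame(resid)) {
    trials <- as.integer(resid$trial)
    rvals <- as.numeric(resid$residual)
  } else {
    trials <- seq_along(resid)
    rvals <- as.numeric(resid)
  }
  T <- length(x)
  ok <- trials >= 2L & trials <= T & !is.na(rvals)
  trials <- trials[ok]; rvals <- rvals[ok]
  if (length(trials) < min_trials) {
    stop(sprintf("insufficient data: %d usable trials (need >= %d)",
                 length(trials), min_trials))
  }

  objective <- function(beta) {
    a <- anticipation(x, beta, n_nodes)[trials]
    f <- suppressWarnings(fit_rt_linear(a, rvals))
    f$objective
  }

  grid_obj <- vapply(grid, objective, numeric(1))
  i0 <- which.min(grid_obj)
  u <- log(grid[i0])
  fu <- grid_obj[i0]
  status <- "interior"
  h <- 1e-4
  for (iter in seq_len(max_iter)) {
    g <- (objective(exp(u + h)) - objective(exp(u - h))) / (2 * h)
    if (abs(g) < grad_tol) break
    step <- 1
    moved <- FALSE
    for (k in seq_len(50L)) {
      u_new <- u - step * g
      if (exp(u_new) > 1000) { status <- "infinite"; u <- u_new; moved <- TRUE; break }
      if (exp(u_new) < 1e-6) { status <- "zero"; u <- u_new; moved <- TRUE; break }
      f_new <- objective(exp(u_new))
      if (f_new < fu) { u <- u_new; fu <- f_new; moved <- TRUE; break }
      step <- step / 2
    }
    if (status != "interior" || !moved) break
  }
  beta <- exp(u)
  if (status == "zero") beta <- 0
  if (status == "infinite") beta <- Inf
  # the returned objective can never exceed the grid minimum
  beta_eval <- if (status == "interior") beta else
    switch(status, zero = 1e-8, infinite = 1000)
  if (status == "interior" && objective(beta) > min(grid_obj)) {
    beta <- grid[i0]
    beta_eval <- beta
  }
  a_fit <- anticipation(x, beta_eval, n_nodes)[trials]
  lin <- suppressWarnings(fit_rt_linear(a_fit, rvals))

  structure(
    list(beta = beta, r0 = lin$r0, r1 = lin$r1, objective = lin$objective,
         status = status,
         grid = data.frame(beta = grid, objective = grid_obj),
         anticipation = a_fit, trials = trials, resid = rvals,
         n = length(trials), n_nodes = n_nodes, x = x,
         call = match.call()),
    class = "beta_fit"
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Temporal-discounting fit\n")
  cat(sprintf("  beta      = %s (%s)\n",
              format(x$beta, digits = 4), x$status))
  cat(sprintf("  r0        = %.4f s\n  r1        = %.4f s\n", x$r0, x$r1))
  cat(sprintf("  RMSE      = %.4f s on %d trials\n", x$objective, x$n))
  invisible(x)
}

#' @export
summary.beta_fit <- function(object, ...) {
  out <- list(
    coefficients = c(beta = object$beta, r0 = object$r0, r1 = object$r1),
    objective = object$objective,
    status = object$status,
    n = object$n,
    grid_range = range(object$grid$beta)
  )
  class(out) <- "summary.beta_fit"
  out
}

#' @export
print.summary.beta_fit <- function(x, ...) {
  cat("Temporal-discounting model fit\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nRMSE: %.4f s   usable trials: %d   status: %s\n",
              x$objective, x$n, x$status))
  invisible(x)
}

#' @export
coef.beta_fit <- function(object, ...) {
  c(beta = object$beta, r0 = object$r0, r1 = object$r1)
}

#' @export
fitted.beta_fit <- function(object, ...) {
  object$r0 + object$r1 * object$anticipation
}

#' @export
residuals.beta_fit <- function(object, ...) {
  object$resid - fitted(object)
}

#' Predict reaction-time residuals for a node sequence
#'
#' @param object A `beta_fit`.
#' @param newdata Optional new node sequence; defaults to the fitted one.
#' @param ... Unused.
#' @return Predicted residual series `r0 + r1 * a(t)` (`NA` for trial 1).
#' @export
predict.beta_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    x <- object$x
  } else {
    x <- as.integer(newdata)
  }
  beta_eval <- switch(object$status, zero = 1e-8, infinite = 1000, object$beta)
  a <- anticipation(x, beta_eval, object$n_nodes)
  object$r0 + object$r1 * a
}

#' Simulate residual reaction times from a fitted model
#'
#' @param object A `beta_fit`.
#' @param nsim Number of simulated series.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of simulated residuals aligned to
#'   the fitted trials (Gaussian noise at the fitted RMSE).
#' @export
simulate.beta_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  out <- replicate(nsim, mu + stats::rnorm(length(mu), sd = object$objective))
  as.data.frame(out)
}

#' Plot the grid objective of a discount-rate fit
#'
#' @param x A `beta_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.beta_fit <- function(x, ...) {
  plot(x$grid$beta, x$grid$objective, log = "x", type = "l",
       xlab = expression(beta), ylab = "RMSE (s)", ...)
  if (is.finite(x$beta) && x$beta > 0) {
    graphics::abline(v = x$beta, lty = 2)
  }
  invisible(x)
}
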