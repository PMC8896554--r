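g_mod <- build_modular_graph()
g_lat <- build_lattice_graph()
A_mod <- transition_matrix(g_mod)
A_lat <- transition_matrix(g_lat)

test_that("analytic map agrees with the geometric-series expansion", {
  for (A in list(A_mod, A_lat)) {
    for (beta in c(0.01, 0.1, 1, 10)) {
      Ah <- map_analytic(A, beta)
      expect_lt(max(abs(unclass(Ah) - map_series_oracle(A, beta))), 1e-8)
      expect_true(all(abs(rowSums(Ah) - 1) < 1e-10))
      expect_true(all(Ah >= 0))
    }
  }
})

test_that("analytic map interpolates between the true matrix and uniformity", {
  expect_lt(max(abs(map_analytic(A_mod, 1000) - A_mod)), 1e-6)
  expect_lt(max(abs(map_analytic(A_mod, 1e-8) - 0.1)), 1e-4)
  # deviation from the true matrix decreases monotonically in beta in the
  # convergent regime (below ~0.1 the sup-norm saturates near its uniform
  # limit and is flat-to-slightly-humped)
  dev <- vapply(exp(seq(log(0.1), log(20), length.out = 12)),
                function(b) max(abs(map_analytic(A_mod, b) - A_mod)),
                numeric(1))
  expect_true(all(diff(dev) < 1e-12))
})

test_that("count updates deposit discounted, unit-mass increments", {
  n <- 10
  # beta -> Inf limit: only the most recent transition counts
  c1 <- update_counts(matrix(0, n, n), history = c(3, 7, 2), next_node = 5,
                      beta = 50)
  expect_equal(c1[2, 5], 1, tolerance = 1e-10)
  expect_equal(sum(c1), 1, tolerance = 1e-12)
  # beta = 0: all past positions weighted equally
  c2 <- update_counts(matrix(0, n, n), history = c(3, 7, 2), next_node = 5,
                      beta = 0)
  expect_equal(c2[c(3, 7, 2), 5], rep(1 / 3, 3))
  # hand-computed two-step history at beta = ln 2: weights 1 and 1/2
  c3 <- update_counts(matrix(0, n, n), history = c(1, 2), next_node = 3,
                      beta = log(2))
  expect_equal(c3[2, 3], 2 / 3)
  expect_equal(c3[1, 3], 1 / 3)
  expect_error(update_counts(matrix(0, n, n), 1:3, 11, 1), "out of range")
})

test_that("sequential learner matches per-trial update accumulation", {
  set.seed(8)
  for (beta in c(0, 0.5, 5)) {
    x <- random_walk(A_lat, 120)
    counts <- matrix(0, 10, 10)
    for (t in 2:120) counts <- update_counts(counts, x[1:(t - 1)], x[t], beta)
    expect_equal(run_counts(x, beta, 10), counts, tolerance = 1e-12)
    # total deposited mass equals the number of observed transitions
    expect_equal(sum(counts), 119, tolerance = 1e-10)
  }
})

test_that("finite-time estimate is row-stochastic with uniform zero rows", {
  counts <- matrix(0, 10, 10)
  counts[3, 7] <- 2.5
  Ah <- map_from_counts(counts)
  expect_equal(Ah[3, ], c(rep(0, 6), 1, 0, 0, 0))
  expect_equal(Ah[1, ], rep(0.1, 10))
  expect_equal(unname(rowSums(Ah)), rep(1, 10))
  # a single sharp observation at high beta gives an indicator row
  c1 <- update_counts(matrix(0, 10, 10), history = 4, next_node = 9, beta = 50)
  expect_equal(map_from_counts(c1)[4, 9], 1)
})

test_that("anticipation tracks the learner's transition estimates", {
  # uniform prediction before any transition is observed
  a <- anticipation(c(1, 2, 3), beta = 1, n_nodes = 10)
  expect_true(is.na(a[1]))
  expect_equal(a[2], 0.1)
  # alternating pair at high beta: anticipation approaches certainty
  x <- rep(c(4, 5), 30)
  a2 <- anticipation(x, beta = 50, n_nodes = 10)
  expect_gt(a2[60], 0.99)
  expect_true(all(a2[-1] >= 0 & a2[-1] <= 1))
  # long-run average anticipation matches the analytic map on traversed edges
  set.seed(13)
  x3 <- random_walk(A_mod, 2000)
  a3 <- anticipation(x3, beta = 1)
  Ah <- map_analytic(A_mod, 1)
  expected <- mean(Ah[cbind(x3[1901:1999], x3[1902:2000])])
  expect_lt(abs(mean(a3[1902:2000]) - expected), 0.05)
})

test_that("linear read-out matches the closed-form normal equations", {
  a <- c(0.1, 0.5, 0.9, 0.3)
  f <- fit_rt_linear(a, 2 - 1 * a)
  expect_equal(f$r0, 2, tolerance = 1e-12)
  expect_equal(f$r1, -1, tolerance = 1e-12)
  expect_equal(f$objective, 0, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:5) {
    a <- runif(60); r <- rnorm(60)
    f <- fit_rt_linear(a, r)
    # independent 2x2 solve
    M <- matrix(c(60, sum(a), sum(a), sum(a^2)), 2)
    cf <- solve(M, c(sum(r), sum(a * r)))
    expect_equal(c(f$r0, f$r1), unname(cf), tolerance = 1e-10)
  }
  expect_warning(f0 <- fit_rt_linear(rep(0.3, 10), rnorm(10)), "constant")
  expect_equal(f0$r1, 0)
})

test_that("uncorrelated noise yields a near-zero slope at the noise floor", {
  set.seed(19)
  slopes <- replicate(20, {
    a <- runif(300); r <- rnorm(300, sd = 0.1)
    f <- fit_rt_linear(a, r)
    c(f$r1, f$objective)
  })
  se <- 0.1 / (sqrt(300) * sd(runif(10000)))
  expect_lt(abs(mean(slopes[1, ])), 3 * se / sqrt(20))
  expect_lt(abs(mean(slopes[2, ]) - 0.1), 0.01)
})

test_that("search grid spans [1e-4, 10] with 100 log-spaced points", {
  gr <- beta_grid()
  expect_length(gr, 100)
  expect_equal(gr[1], 1e-4)
  expect_equal(gr[100], 10)
  expect_equal(diff(log(gr)), rep(diff(log(c(1e-4, 10))) / 99, 99),
               tolerance = 1e-12)
})

test_that("discount-rate fit honours the minimizer contract", {
  set.seed(29)
  x <- random_walk(A_mod, 600)
  a <- anticipation(x, 0.3)
  resid <- -0.3 * a + rnorm(600, sd = 0.05)
  fit <- fit_beta(x, resid)
  expect_s3_class(fit, "beta_fit")
  expect_true(all(fit$objective <= fit$grid$objective + 1e-12))
  expect_error(fit_beta(x[1:60], resid[1:20]), "insufficient")
  # methods behave
  expect_equal(unname(coef(fit)["beta"]), fit$beta)
  expect_length(fitted(fit), fit$n)
  expect_equal(residuals(fit), fit$resid - fitted(fit))
  expect_output(print(fit), "beta")
  p <- predict(fit)
  expect_length(p, 600)
})

test_that("white-noise residuals do not manufacture discounting evidence", {
  set.seed(37)
  x <- random_walk(A_mod, 600)
  fit <- fit_beta(x, rnorm(600, sd = 0.1))
  flat <- diff(range(fit$grid$objective)) /
    (sd(fit$grid$objective) + 1e-12)
  expect_true(fit$status == "zero" || abs(fit$r1) < 0.05 ||
                diff(range(fit$grid$objective)) < 0.01)
})

test_that("the discount rate is recovered from model-generated residuals", {
  set.seed(41)
  est <- vapply(1:8, function(s) {
    x <- random_walk(A_mod, 1000)
    a <- anticipation(x, 0.2)
    resid <- -0.3 * a + rnorm(1000, sd = 0.075)
    f <- fit_beta(x, resid)
    if (f$status == "interior") f$beta else NA_real_
  }, numeric(1))
  expect_gt(median(est, na.rm = TRUE), 0.1)
  expect_lt(median(est, na.rm = TRUE), 0.4)
})

test_that("finite-time estimates converge toward the analytic map", {
  set.seed(53)
  x <- random_walk(A_mod, 1000)
  Ah_inf <- map_analytic(A_mod, 1)
  lt <- lower.tri(Ah_inf)
  corr_at <- function(t) {
    Ah_t <- map_from_counts(run_counts(x[1:t], 1, 10))
    cor(unclass(Ah_t)[lt], unclass(Ah_inf)[lt])
  }
  expect_gt(corr_at(1000), 0.9)
  expect_gt(corr_at(1000), corr_at(100))
})
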