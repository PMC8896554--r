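test_that("window starts and counts follow the sliding-block definition", {
  w <- sliding_windows(1000, 500, 100)
  expect_equal(w$starts, c(1L, 101L, 201L, 301L, 401L, 501L))
  expect_equal(length(sliding_windows(500, 500, 100)$starts), 1L)
  expect_error(sliding_windows(400, 500), "exceeds")
  # formula vs exhaustive enumeration over random designs
  set.seed(44)
  for (k in 1:100) {
    n <- sample(50:2000, 1)
    width <- sample(10:n, 1)
    step <- sample(1:300, 1)
    w <- sliding_windows(n, width, step)
    starts <- c()
    s <- 1
    while (s + width - 1 <= n) { starts <- c(starts, s); s <- s + step }
    expect_equal(w$starts, as.integer(starts))
    expect_equal(length(w$starts), floor((n - width) / step) + 1)
  }
})

test_that("windowed correlations normalize to the full-data value", {
  set.seed(46)
  g <- build_modular_graph()
  tpl <- latent_template(g, 1)
  cfg <- synth_config(seed = 5, n_channels = 2, n_trials = 200, fs = 128)
  e <- truncate_epochs(gen_neural(cfg, tpl, structured_channels = 1:2))
  w <- sliding_windows(200, width = 200)   # single full-width window
  out <- windowed_template_corr(e, list(latent = tpl), w)
  expect_equal(out$r_normalized, rep(1, nrow(out)), tolerance = 1e-12)
  # stationary structure: final-window normalized correlation near 1
  w2 <- sliding_windows(200, width = 100, step = 50)
  out2 <- windowed_template_corr(e, list(latent = tpl), w2)
  last <- out2[out2$window == max(out2$window), ]
  expect_true(all(abs(last$r_normalized - 1) < 0.15))
})

test_that("structure planted late in the session grows across windows", {
  set.seed(48)
  g <- build_modular_graph()
  tpl <- latent_template(g, 1)
  hits <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    cfg <- synth_config(seed = 100 + s, n_channels = 1, n_trials = 300,
                        fs = 128, snr = 1.5)
    e <- gen_neural(cfg, tpl, structured_channels = 1L)
    # remove the pattern from the first half of trials
    noise_only <- gen_neural(synth_config(seed = 100 + s, n_channels = 1,
                                          n_trials = 300, fs = 128),
                             tpl, structured_channels = integer(0),
                             labels = e$labels, rts = e$rts)
    e$data[, , 1:150] <- noise_only$data[, , 1:150]
    et <- truncate_epochs(e)
    w <- sliding_windows(300, width = 150, step = 50)
    out <- windowed_template_corr(et, list(latent = tpl), w)
    rho <- cor(out$window, out$r, method = "spearman")
    if (!is.na(rho) && rho > 0) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("windowed discount fits are stable and track regime changes", {
  set.seed(52)
  g <- build_modular_graph()
  A <- transition_matrix(g)
  # stationary learner: per-window medians over seeds stay within a broad band
  ests <- replicate(6, {
    x <- random_walk(A, 1000)
    a <- anticipation(x, 0.3)
    resid <- data.frame(trial = 1:1000,
                        residual = -0.3 * a + rnorm(1000, sd = 0.05))
    resid <- resid[-1, ]
    wb <- windowed_beta(x, resid, sliding_windows(1000, 500, 250))
    wb$beta
  })
  meds <- apply(ests, 1L, median, na.rm = TRUE)
  expect_true(all(meds > 0.05 & meds < 1.5))
  # discounting switch mid-session: later window exceeds the first
  diffs <- replicate(5, {
    x <- random_walk(A, 1000)
    a1 <- anticipation(x[1:500], 0.05)
    a2 <- anticipation(x[501:1000], 1)
    resid <- data.frame(trial = 2:1000,
                        residual = -0.3 * c(a1[-1], 0.1, a2[-1]) +
                          rnorm(999, sd = 0.03))
    wb <- windowed_beta(x, resid, sliding_windows(1000, 500, 500))
    wb$beta[2] - wb$beta[1]
  })
  expect_gt(median(diffs, na.rm = TRUE), 0)
  # single full-width window reproduces the plain fit
  x <- random_walk(A, 600, seed = 9)
  a <- anticipation(x, 0.3)
  resid <- data.frame(trial = 1:600,
                      residual = -0.3 * a + rnorm(600, sd = 0.05))
  resid <- resid[-1, ]
  wb1 <- windowed_beta(x, resid, sliding_windows(600, 600))
  f <- fit_beta(x, resid)
  expect_equal(wb1$beta[1], f$beta, tolerance = 1e-10)
})

test_that("convergence curves rise with trials and with the discount rate", {
  g <- build_modular_graph()
  cc1 <- convergence_curve(g, beta = 1, n_trials = 600, n_walks = 8, seed = 61)
  expect_true(is.na(cc1$correlation[2]))
  expect_gt(cc1$correlation[600], 0.9)
  expect_gt(cc1$correlation[600], cc1$correlation[100])
  cc01 <- convergence_curve(g, beta = 0.1, n_trials = 600, n_walks = 8,
                            seed = 61)
  expect_gt(cc1$correlation[200], cc01$correlation[200])
  # near-monotone after early trials (small sampling violations tolerated)
  late <- cc1$correlation[100:600]
  expect_lt(mean(diff(late) < -0.02), 0.05)
})
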