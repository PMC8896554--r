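test_that("truncation arithmetic respects alignment and the 200-ms floor", {
  set.seed(2)
  e <- epoch_array(array(rnorm(2 * 300 * 6), c(2, 300, 6)), fs = 512,
                   labels = c(1, 2, 3, 1, 2, 3),
                   rts = c(0.25, 0.30, 0.40, 0.28, 0.33, 0.50))
  et <- truncate_epochs(e)
  expect_equal(dim(et$data)[2], 128)           # floor(0.25 * 512)
  expect_equal(length(et$labels), 6)
  # sub-200 ms shortest trial: floor kicks in and the trial is discarded
  e2 <- e; e2$rts[1] <- 0.15
  et2 <- truncate_epochs(e2)
  expect_equal(dim(et2$data)[2], ceiling(0.2 * 512))
  expect_false(1 %in% et2$trial)
  # index-arithmetic oracle for all three alignments
  ei <- epoch_array(array(as.numeric(seq_len(50 * 3)), c(1, 50, 3)), fs = 100,
                    labels = 1:3, rts = c(0.30, 0.40, 0.45))
  for (al in c("stimulus", "middle", "response")) {
    et3 <- truncate_epochs(ei, al)
    L <- dim(et3$data)[2]
    expect_equal(L, 30)
    v <- 45
    idx <- switch(al,
      stimulus = 1:L,
      response = (v - L + 1):v,
      middle = c(1:ceiling(L / 2), (v - (L - ceiling(L / 2)) + 1):v))
    expect_equal(et3$data[1, , 3], ei$data[1, idx, 3])
  }
  e$rts[] <- 0.1
  expect_error(truncate_epochs(e), "shorter")
})

test_that("noiseless cross-validated distances equal pattern distances", {
  set.seed(4)
  P <- matrix(rnorm(10 * 16), 10, 16)
  e <- make_epochs(P, n_rep = 3, noise_sd = 0)
  d <- cv_euclidean_rdm(e)
  ref <- as.matrix(dist(P))^2 / 16
  expect_equal(unclass(d), ref, tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(d)))
  expect_equal(diag(d), rep(0, 10))
  # invariant to trial order within conditions
  perm <- sample(30)
  e2 <- e
  e2$data <- e$data[, , perm, drop = FALSE]
  e2$labels <- e$labels[perm]
  expect_equal(unclass(cv_euclidean_rdm(e2)), unclass(d), tolerance = 1e-10)
})

test_that("gram-based estimator matches the direct fold-loop oracle", {
  set.seed(6)
  P <- matrix(rnorm(4 * 12), 4, 12)
  labels <- c(rep(1, 3), rep(2, 5), rep(3, 4), rep(4, 3))
  e <- make_epochs(P, n_rep = 1, noise_sd = 1, labels = labels)
  d <- cv_euclidean_rdm(e)
  X <- matrix(e$data[1, , ], nrow = 12)
  for (a in 1:3) for (b in (a + 1):4) {
    expect_equal(d[a, b],
                 cv_dist_oracle(X[, labels == a, drop = FALSE],
                                X[, labels == b, drop = FALSE]),
                 tolerance = 1e-10)
  }
  e$labels[e$labels == 2][-1] <- 1   # leave condition 2 a single trial
  expect_error(cv_euclidean_rdm(e), "at least 2")
})

test_that("cross-validated distance is unbiased for identical-mean conditions", {
  set.seed(12)
  vals <- replicate(60, {
    e <- make_epochs(matrix(0, 2, 10), n_rep = 8, noise_sd = 1)
    cv_euclidean_rdm(e)[1, 2]
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(60))
})

test_that("template correlation follows the lower triangle and polarity", {
  g <- build_modular_graph()
  tpl <- latent_template(g, 1)
  d <- as_rdm(max(tpl) + 1 - unclass(tpl), "dissimilarity")
  expect_equal(template_corr(d, tpl), 1, tolerance = 1e-12)
  expect_error(template_corr(d, as_rdm(matrix(1, 10, 10), "similarity")),
               "undefined")
  set.seed(14)
  for (k in 1:5) {
    m1 <- matrix(rnorm(100), 10); m1 <- m1 + t(m1); diag(m1) <- 0
    m2 <- matrix(rnorm(100), 10); m2 <- m2 + t(m2); diag(m2) <- 0
    lt <- lower.tri(m1)
    expect_equal(template_corr(as_rdm(m1), as_rdm(m2)),
                 pearson_oracle(m1[lt], m2[lt]), tolerance = 1e-10)
    expect_equal(template_corr(as_rdm(m1), as_rdm(m2, "similarity")),
                 -pearson_oracle(m1[lt], m2[lt]), tolerance = 1e-10)
  }
})

test_that("visual template is a translation-invariant distance map", {
  # collinear unit-spaced row: distance equals index difference
  v <- visual_template()
  expect_equal(v[1, 4], 3)
  expect_equal(v[2, 3], 1)
  set.seed(16)
  pos <- matrix(rnorm(20), 10, 2)
  v1 <- visual_template(pos)
  v2 <- visual_template(sweep(pos, 2, c(5, -3), "+"))
  expect_equal(unclass(v1), unclass(v2), tolerance = 1e-12)
  # brute-force pairwise distances
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(v1[i, j], sqrt(sum((pos[i, ] - pos[j, ])^2)),
                 tolerance = 1e-12)
  }
  # assignment permutes node identities
  perm <- sample(10)
  v3 <- visual_template(pos, assignment = perm)
  expect_equal(v3[1, 2], v1[perm[1], perm[2]])
})

test_that("circular-shift null preserves support and reproduces the observed
           value at a degenerate shift", {
  set.seed(18)
  P <- matrix(rnorm(10 * 8), 10, 8)
  e <- make_epochs(P, n_rep = 4, noise_sd = 0.5)
  tpl <- latent_template(build_modular_graph(), 1)
  nd <- circular_shift_null(e, tpl, n_perm = 40, seed = 3)
  expect_length(nd$correlations, 40)
  T <- length(e$labels)
  expect_true(all(nd$splits >= 1 & nd$splits <= T - 1))
  # degenerate identity reordering reproduces the observed correlation
  X <- matrix(e$data[1, , ], nrow = dim(e$data)[2])
  d0 <- cogmap:::rdm_from_gram(crossprod(X), e$labels, p = seq_len(T),
                               veclen = nrow(X))
  expect_equal(template_corr(d0, tpl),
               template_corr(cv_euclidean_rdm(e), tpl), tolerance = 1e-12)
})

test_that("contact selection applies both criteria, visual only the first", {
  set.seed(22)
  nulls <- matrix(rnorm(100 * 3, sd = 0.1), 100, 3)
  r_latent <- c(0.9, 0.9, quantile(nulls[, 3], 0.5))
  r_exact <- c(0.5, 0.95, 0)
  sel <- select_contacts(r_latent, r_exact, nulls,
                         r_visual = c(0.9, -0.9, 0.9),
                         nulls_visual = nulls)
  expect_true(sel$selected_latent[1])
  expect_false(sel$selected_latent[2])   # fails criterion 2
  expect_false(sel$selected_latent[3])   # fails the null criterion
  expect_equal(sel$selected_visual, c(TRUE, FALSE, TRUE))
})

test_that("planted-template channels are selected, noise channels rarely", {
  g <- build_modular_graph()
  tpl <- latent_template(g, 1)
  cfg <- synth_config(seed = 91, n_channels = 12, n_trials = 400, fs = 128)
  e <- truncate_epochs(gen_neural(cfg, tpl, structured_channels = c(2, 7)))
  sel <- rsa_select(e, tpl, exact_template(g), n_perm = 100, seed = 8)
  expect_true(all(sel$selected_latent[c(2, 7)]))
  expect_lte(sum(sel$selected_latent[-c(2, 7)]), 1)
  expect_true(all(sel$r_latent[c(2, 7)] > sel$r_exact[c(2, 7)]))
})
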