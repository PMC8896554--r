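#' Configuration for the synthetic sequence-learning experiment
#'
#' Bundles the generating parameters of the emulated design: a 1000-trial
#' random walk on a 10-node latent graph, reaction times produced by the
#' linear anticipation read-out `r0 + r1 * a(t)` plus a recency effect and
#' Gaussian noise, and multichannel evoked epochs whose condition-mean
#' geometry embeds a chosen similarity template at a controlled
#' signal-to-noise ratio.
#'
#' Defaults reflect the emulated design: 1000 trials, accuracy 0.97,
#' baseline reaction time `r0 = 0.7` s, anticipation slope `r1 = -0.3` s
#' (faster when anticipated), residual noise `|r1|/4`, recency effect
#' 0.05 s per log-trial unit, 512 Hz sampling, 20 channels.
#'
#' @param graph `"modular"` or `"lattice"`.
#' @param beta_true Generating discount rate (default 0.2).
#' @param r0,r1 Intercept and anticipation slope, seconds.
#' @param noise_sd Residual reaction-time noise SD, seconds.
#' @param gamma Recency effect, seconds per log-trial unit.
#' @param n_trials Number of trials (at least 100; default 1000).
#' @param n_channels Number of recording channels (default 20).
#' @param fs Sampling rate in Hz (default 512).
#' @param snr Ratio of condition-mean pattern norm to noise norm (default 2).
#' @param p_correct Per-trial probability of a correct response (default 0.97).
#' @param rt_noise `"gaussian"` (default) or `"lognormal"` residual noise.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(graph = c("modular", "lattice"), beta_true = 0.2,
                         r0 = 0.7, r1 = -0.3, noise_sd = abs(r1) / 4,
                         gamma = 0.05, n_trials = 1000L, n_channels = 20L,
                         fs = 512, snr = 2, p_correct = 0.97,
                         rt_noise = c("gaussian", "lognormal"), seed = 1L) {
  graph <- match.arg(graph)
  rt_noise <- match.arg(rt_noise)
  stopifnot(n_trials >= 100L, snr > 0, noise_sd > 0)
  structure(
    list(graph = graph, beta_true = beta_true, r0 = r0, r1 = r1,
         noise_sd = noise_sd, gamma = gamma, n_trials = as.integer(n_trials),
         n_channels = as.integer(n_channels), fs = fs, snr = snr,
         p_correct = p_correct, rt_noise = rt_noise, seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_graph <- function(c) {
  if (c$graph == "modular") build_modular_graph() else build_lattice_graph()
}

#' Generate synthetic behaviour from the temporal-discounting model
#'
#' Draws a random walk on the configured latent graph and produces reaction
#' times `rt(t) = r0 + r1 * a(t) + gamma * recency(t) + noise`, where `a(t)`
#' is the anticipation of a discounted-count learner with the configured
#' generating `beta_true`. Correctness is Bernoulli. Stimuli are randomly
#' assigned to keyboard positions; finger, hand, and hand-transition
#' covariates derive from that assignment. All generating values are kept so
#' recovery simulations can compare against ground truth.
#'
#' @param c A `synth_config`.
#' @return A list of class `synth_behavior`: `x` (node sequence),
#'   `behavior` (trial table: `trial`, `node`, `rt`, `correct`, `stage`,
#'   `session`, `finger`, `hand`, `hand_transition`, `recency`), `a_true`
#'   (generating anticipation series), `assignment` (node-to-key
#'   permutation), and `config`.
#' @export
gen_behavior <- function(c) {
  stopifnot(inherits(c, "synth_config"))
  set.seed(c$seed)
  g <- synth_graph(c)
  A <- transition_matrix(g)
  n <- nrow(A)
  x <- random_walk(A, c$n_trials)
  a <- anticipation(x, c$beta_true, n)
  a[1] <- 1 / n                     # no prediction exists for the first trial
  rec <- recency_covariate(x)
  eps <- if (c$rt_noise == "gaussian") {
    stats::rnorm(c$n_trials, 0, c$noise_sd)
  } else {
    sdl <- sqrt(log(1 + (c$noise_sd / 1)^2))
    (stats::rlnorm(c$n_trials, -sdl^2 / 2, sdl) - 1)
  }
  rt <- pmax(c$r0 + c$r1 * a + c$gamma * rec + eps, 0.051)
  correct <- stats::rbinom(c$n_trials, 1L, c$p_correct) == 1L
  assignment <- sample.int(n)       # node -> keyboard position
  key <- assignment[x]
  hand <- ifelse(key <= ceiling(n / 2), "L", "R")
  behavior <- data.frame(
    trial = seq_len(c$n_trials),
    node = x,
    rt = rt,
    correct = correct,
    stage = ceiling(seq_len(c$n_trials) / 250),
    session = 1L,
    finger = key,
    hand = hand,
    hand_transition = c(FALSE, hand[-1] != hand[-c$n_trials]),
    recency = rec
  )
  structure(list(x = x, behavior = behavior, a_true = a,
                 assignment = assignment, config = c),
            class = "synth_behavior")
}

#' Generate synthetic evoked epochs embedding a similarity template
#'
#' Builds a multichannel epoch array whose condition-mean activity geometry
#' matches a chosen template on a designated subset of channels, with all
#' remaining channels pure noise. The template is converted to a target
#' squared-distance structure (similarity templates are flipped), embedded by
#' classical MDS into at most `n_nodes - 1` dimensions, and the embedding
#' coordinates are tiled along the time axis of each structured channel so
#' that every structured channel individually carries the full geometry. The
#' per-node mean patterns are scaled so that the ratio of the mean pattern
#' norm to the expected noise norm equals `snr`. Trial lengths are set by
#' simulated reaction times.
#'
#' @param c A `synth_config`.
#' @param template An `rdm` (similarity or dissimilarity polarity) of size
#'   `n_nodes`.
#' @param structured_channels Integer indices of channels carrying the
#'   pattern (may be empty for a pure-noise array).
#' @param labels,rts Optional node sequence and reaction times; generated
#'   from the config when omitted.
#' @return An `epoch_array` (stimulus-aligned, untruncated), with the mean
#'   patterns attached as attribute `"patterns"`.
#' @export
gen_neural <- function(c, template, structured_channels = integer(0),
                       labels = NULL, rts = NULL) {
  stopifnot(inherits(c, "synth_config"))
  set.seed(c$seed + 1L)
  n <- nrow(template)
  if (is.null(labels)) {
    labels <- random_walk(transition_matrix(synth_graph(c)), c$n_trials)
  }
  if (is.null(rts)) {
    rts <- pmax(stats::rnorm(length(labels), c$r0, 0.15), 0.25)
  }
  Tn <- length(labels)
  Lmax <- ceiling(max(rts) * c$fs)
  # target squared distances: flip similarity templates so that larger
  # similarity means closer patterns
  v <- unclass(template)
  if (identical(attr(template, "polarity"), "similarity")) {
    f <- max(v[row(v) != col(v)]) - v
  } else {
    f <- v
  }
  f <- (f + t(f)) / 2
  diag(f) <- 0
  f[f < 0] <- 0
  # Lingoes additive constant: shifting all off-diagonal squared distances
  # keeps them affine in the template while making them exactly Euclidean
  J <- diag(n) - 1 / n
  lam <- eigen(-J %*% f %*% J / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-12) {
    f <- f + 2 * abs(min(lam)) * (1 - diag(n))
  }
  Demb <- sqrt(f)                 # squared pattern distances track the template
  kmax <- min(n - 1L, Lmax)
  if (kmax < 1L) stop("infeasible embedding dimension")
  co <- suppressWarnings(stats::cmdscale(Demb, k = kmax))
  if (NCOL(co) < 1L) stop("template admits no Euclidean embedding")
  co <- as.matrix(co)
  k <- ncol(co)
  patterns <- co[, ((seq_len(Lmax) - 1L) %% k) + 1L, drop = FALSE]
  # scale: mean pattern norm over nodes = snr * expected unit-noise norm
  sf <- c$snr * sqrt(Lmax) / mean(sqrt(rowSums(patterns^2)))
  patterns <- patterns * sf
  data <- array(stats::rnorm(c$n_channels * Lmax * Tn),
                c(c$n_channels, Lmax, Tn))
  for (ch in structured_channels) {
    data[ch, , ] <- data[ch, , ] + t(patterns[labels, , drop = FALSE])
  }
  e <- epoch_array(data, fs = c$fs, labels = labels, rts = rts,
                   alignment = "stimulus")
  attr(e, "patterns") <- patterns
  e
}

#' Generate a continuous recording with planted interictal discharges
#'
#' Pink-noise (1/f) background on every channel with biphasic 70-ms spike
#' transients injected synchronously on a random subset of at least
#' `min_channels` channels at each ground-truth time. Spike times keep a
#' minimum separation (collisions are redrawn).
#'
#' @param n_channels Number of channels (default 20).
#' @param duration Recording length in seconds (at least 10; default 120).
#' @param n_spikes Number of planted discharges (default 30).
#' @param snr Spike peak amplitude relative to background SD (default 5).
#' @param fs Sampling rate in Hz (default 512).
#' @param min_channels,max_channels Range of channels per discharge
#'   (defaults 4 and `min_channels + 4`).
#' @param seed Optional integer seed.
#' @return List: `signals` (`channels x samples`), `fs`, `spike_times`
#'   (seconds), `spike_channels` (list of channel sets).
#' @export
gen_ied_recording <- function(n_channels = 20L, duration = 120, n_spikes = 30L,
                              snr = 5, fs = 512, min_channels = 4L,
                              max_channels = min_channels + 4L,
                              seed = NULL) {
  if (duration < 10) stop("duration must be at least 10 s")
  if (!is.null(seed)) set.seed(seed)
  N <- round(duration * fs)
  signals <- matrix(0, n_channels, N)
  for (ch in seq_len(n_channels)) {
    signals[ch, ] <- pink_noise(N)
  }
  # biphasic spike: derivative-of-Gaussian over 70 ms, unit peak
  tt <- seq(-3, 3, length.out = round(0.070 * fs))
  spike <- -tt * exp(-tt^2 / 2)
  spike <- spike / max(abs(spike)) * snr
  times <- numeric(0)
  guard <- 0
  while (length(times) < n_spikes && guard < 10000L) {
    cand <- stats::runif(1, 1, duration - 1)
    if (all(abs(cand - times) > 0.5)) times <- c(times, cand)
    guard <- guard + 1
  }
  times <- sort(times)
  chans <- vector("list", length(times))
  for (k in seq_along(times)) {
    rng <- min_channels:min(n_channels, max_channels)
    nc <- if (length(rng) == 1L) rng else sample(rng, 1L)
    chans[[k]] <- sort(sample.int(n_channels, nc))
    i0 <- round(times[k] * fs)
    idx <- i0:(i0 + length(spike) - 1L)
    for (ch in chans[[k]]) signals[ch, idx] <- signals[ch, idx] + spike
  }
  list(signals = signals, fs = fs, spike_times = times,
       spike_channels = chans)
}

# 1/f-amplitude noise via spectral shaping, unit variance
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  x <- Re(stats::fft(X / sqrt(f), inverse = TRUE))
  as.numeric(scale(x))
}
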