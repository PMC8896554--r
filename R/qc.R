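#' Channel-quality metrics for continuous recordings
#'
#' Per-channel metrics used to reject noisy intracranial channels:
#' * `line_length` — sum of absolute first differences over the recording
#'   (sensitive to high-frequency noise);
#' * `kurtosis_z` — kurtosis of the trace, z-scored across channels
#'   (sensitive to spikes and drift);
#' * `psd_dissim_z` — average of one minus the Spearman rank correlation of
#'   the channel's power spectral density with every other channel, z-scored
#'   across channels (sensitive to line noise and isolated artifacts). The
#'   raw dissimilarity lies in `[0, 2]`.
#'
#' Constant channels have undefined kurtosis/PSD metrics; their metrics are
#' `NA` and they are flagged automatically by [reject_channels()].
#'
#' @param signals Numeric matrix `channels x samples`.
#' @param fs Sampling rate in Hz.
#' @return A data.frame with one row per channel: `line_length`,
#'   `kurtosis_z`, `psd_dissim`, `psd_dissim_z`.
#' @export
channel_metrics <- function(signals, fs) {
  signals <- as.matrix(signals)
  C <- nrow(signals)
  if (C < 2L) stop("need at least 2 channels")
  line_length <- apply(signals, 1L, function(x) sum(abs(diff(x))))
  kurt <- apply(signals, 1L, function(x) {
    if (stats::sd(x) == 0) NA_real_ else e1071::kurtosis(x)
  })
  psd <- lapply(seq_len(C), function(ch) {
    x <- signals[ch, ]
    if (stats::sd(x) == 0) return(NULL)
    stats::spec.pgram(stats::ts(x, frequency = fs), spans = c(11, 11),
                      taper = 0.1, detrend = TRUE, plot = FALSE)$spec
  })
  dis <- rep(NA_real_, C)
  for (ch in seq_len(C)) {
    if (is.null(psd[[ch]])) next
    others <- setdiff(which(!vapply(psd, is.null, logical(1))), ch)
    if (length(others) == 0L) next
    rho <- vapply(others, function(o) {
      suppressWarnings(stats::cor(psd[[ch]], psd[[o]], method = "spearman"))
    }, numeric(1))
    dis[ch] <- mean(1 - rho)
  }
  zsc <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)) + 0 * v)  # keep NAs
    (v - mean(v, na.rm = TRUE)) / s
  }
  data.frame(
    channel = seq_len(C),
    line_length = line_length,
    kurtosis_z = zsc(kurt),
    psd_dissim = dis,
    psd_dissim_z = zsc(dis)
  )
}

#' Reject channels by quality thresholds
#'
#' Flags a channel when its line length exceeds three times the mean line
#' length, its z-scored kurtosis exceeds 1.5, or its z-scored PSD
#' dissimilarity exceeds 1.5. Channels with undefined metrics (constant
#' traces) are flagged.
#'
#' @param m Metrics data.frame from [channel_metrics()].
#' @param ll_mult Line-length multiplier (default 3).
#' @param kurt_thr,psd_thr z-score thresholds (default 1.5).
#' @return Logical vector, `TRUE` = reject.
#' @export
reject_channels <- function(m, ll_mult = 3, kurt_thr = 1.5, psd_thr = 1.5) {
  flags <- m$line_length > ll_mult * mean(m$line_length)
  flags <- flags | ifelse(is.na(m$kurtosis_z), TRUE, m$kurtosis_z > kurt_thr)
  flags <- flags | ifelse(is.na(m$psd_dissim_z), TRUE, m$psd_dissim_z > psd_thr)
  unname(flags)
}

# analytic signal via frequency-domain construction (no installed package
# provides a Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# histogram mode over 64 bins (the envelope is continuous; its mode is
# estimated from the binned density)
hist_mode <- function(v, bins = 64L) {
  b <- seq(min(v), max(v), length.out = bins + 1L)
  if (b[1] == b[bins + 1L]) return(v[1])
  counts <- tabulate(findInterval(v, b, rightmost.closed = TRUE), nbins = bins)
  mids <- (b[-1] + b[-(bins + 1L)]) / 2
  mids[which.max(counts)]
}

#' Detect interictal epileptiform discharges
#'
#' Hilbert-envelope IED detector: each channel is downsampled to 200 Hz,
#' band-pass filtered to 10-60 Hz (4th-order Butterworth, zero-phase), and
#' its envelope computed as the squared magnitude of the analytic signal. In
#' 5-s windows with 4-s overlap a threshold `k0 * (mode + median)` of the
#' envelope is computed (mode estimated from a 64-bin histogram); samples
#' above threshold in any covering window mark candidate discharges, and
#' each contiguous supra-threshold run becomes one event timed at its
#' envelope peak. A spatial filter then keeps only events that co-occur
#' (within +/- 50 ms) with events on at least `min_cochannels` other
#' channels, removing isolated single-channel artifacts.
#'
#' @param signals Numeric matrix `channels x samples`.
#' @param fs Sampling rate in Hz (must be at least 200).
#' @param k0 Threshold scale (default 3.65).
#' @param min_cochannels Minimum number of other channels with co-occurring
#'   events (default 3).
#' @param window_s,overlap_s Window length and overlap in seconds (defaults
#'   5 and 4).
#' @return A data.frame of events: `channel`, `time` (seconds), `passed`
#'   (spatial-filter flag).
#' @export
detect_ieds <- function(signals, fs, k0 = 3.65, min_cochannels = 3L,
                        window_s = 5, overlap_s = 4) {
  signals <- as.matrix(signals)
  if (fs < 200) stop("sampling rate below 200 Hz; cannot downsample to 200 Hz")
  if (ncol(signals) / fs < window_s) stop("recording shorter than one window")
  fs2 <- 200
  events <- list()
  for (ch in seq_len(nrow(signals))) {
    x <- signals[ch, ]
    xr <- if (fs == fs2) x else as.numeric(signal::resample(x, fs2, fs))
    bf <- signal::butter(4, c(10, 60) / (fs2 / 2), type = "pass")
    y <- as.numeric(signal::filtfilt(bf, xr))
    env <- Mod(analytic_signal(y))^2
    # the power envelope is heavy-tailed with mode at zero, so the
    # mode + median statistic is taken on the amplitude scale (Rayleigh-like
    # background); thresholding is equivalent on either scale
    amp <- sqrt(env)
    n <- length(env)
    win <- round(window_s * fs2)
    step <- round((window_s - overlap_s) * fs2)
    starts <- seq(1L, max(1L, n - win + 1L), by = step)
    if (starts[length(starts)] + win - 1L < n) starts <- c(starts, n - win + 1L)
    supra <- logical(n)
    for (s in starts) {
      idx <- s:min(s + win - 1L, n)
      av <- amp[idx]
      thr <- k0 * (hist_mode(av) + stats::median(av))
      supra[idx] <- supra[idx] | (env[idx] > thr^2)
    }
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts_r <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seg <- starts_r[k]:ends[k]
      peak <- seg[which.max(env[seg])]
      events[[length(events) + 1L]] <-
        data.frame(channel = ch, time = (peak - 1) / fs2)
    }
  }
  if (length(events) == 0L) {
    return(data.frame(channel = integer(), time = numeric(),
                      passed = logical()))
  }
  ev <- do.call(rbind, events)
  ev$passed <- vapply(seq_len(nrow(ev)), function(i) {
    near <- abs(ev$time - ev$time[i]) <= 0.050 & ev$channel != ev$channel[i]
    length(unique(ev$channel[near])) >= min_cochannels
  }, logical(1))
  ev[order(ev$time, ev$channel), , drop = FALSE]
}

#' Reject trials containing interictal discharges
#'
#' @param events Event data.frame from [detect_ieds()].
#' @param onsets,offsets Trial onset/offset times in seconds.
#' @param passed_only Use only events that passed the spatial filter
#'   (default `TRUE`).
#' @return Logical vector per trial, `TRUE` = reject.
#' @export
reject_ied_trials <- function(events, onsets, offsets, passed_only = TRUE) {
  stopifnot(length(onsets) == length(offsets))
  tms <- if (passed_only && "passed" %in% names(events)) {
    events$time[events$passed]
  } else {
    events$time
  }
  vapply(seq_along(onsets), function(i) {
    any(tms >= onsets[i] & tms <= offsets[i])
  }, logical(1))
}

#' Optional preprocessing hooks
#'
#' Standard plumbing provided for convenience: a zero-phase Butterworth
#' stop-band filter for line noise and harmonics, and common-average
#' referencing within channel groups. Neither is required by the analysis
#' functions.
#'
#' @param signals Numeric matrix `channels x samples`.
#' @param fs Sampling rate in Hz.
#' @param freqs Line frequencies to notch (default 60, 120, 180 Hz).
#' @param width Stop-band width in Hz (default 1).
#' @return The filtered signal matrix.
#' @export
notch_filter <- function(signals, fs, freqs = c(60, 120, 180), width = 1) {
  signals <- as.matrix(signals)
  for (f0 in freqs) {
    if (f0 + width / 2 >= fs / 2) next
    bf <- signal::butter(4, c(f0 - width / 2, f0 + width / 2) / (fs / 2),
                         type = "stop")
    for (ch in seq_len(nrow(signals))) {
      signals[ch, ] <- as.numeric(signal::filtfilt(bf, signals[ch, ]))
    }
  }
  signals
}

#' @rdname notch_filter
#' @param groups Integer group label per channel (e.g. electrode shaft);
#'   default one group.
#' @export
car_reference <- function(signals, groups = NULL) {
  signals <- as.matrix(signals)
  if (is.null(groups)) groups <- rep(1L, nrow(signals))
  for (gr in unique(groups)) {
    idx <- which(groups == gr)
    ref <- colMeans(signals[idx, , drop = FALSE])
    signals[idx, ] <- sweep(signals[idx, , drop = FALSE], 2L, ref)
  }
  signals
}
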