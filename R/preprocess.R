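#' Preprocessing configuration
#'
#' Parameters of the epoch-level preprocessing chain: zero-phase band-pass
#' filtering (0.1-100 Hz), probability-based noisy-channel detection at 5 SD,
#' average re-referencing, downsampling to 256 Hz, epoching with per-epoch
#' linear detrending, and cropping to -100..1000 ms.
#'
#' @param highpass_hz,lowpass_hz band edges (Hz); zero-phase Butterworth.
#' @param hp_order,lp_order Butterworth orders of the two filter sections.
#' @param target_rate_hz rate (Hz) after anti-aliased resampling.
#' @param bad_channel_sd_threshold z-score threshold on the per-channel
#'   deviance of the amplitude distribution (see [detect_bad_channels()]).
#' @param epoch_window_ms initial epoch window around each onset (ms).
#' @param crop_window_ms window retained after detrending (ms).
#' @return A list of class `"preproc_config"`.
#' @export
preproc_config <- function(highpass_hz = 0.1, lowpass_hz = 100,
                           hp_order = 2L, lp_order = 4L,
                           target_rate_hz = 256,
                           bad_channel_sd_threshold = 5,
                           epoch_window_ms = c(-533, 1067),
                           crop_window_ms = c(-100, 1000)) {
  if (!(0 < highpass_hz && highpass_hz < lowpass_hz))
    stop("need 0 < highpass_hz < lowpass_hz")
  if (bad_channel_sd_threshold <= 0) stop("threshold must be positive")
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 hp_order = as.integer(hp_order),
                 lp_order = as.integer(lp_order),
                 target_rate_hz = target_rate_hz,
                 bad_channel_sd_threshold = bad_channel_sd_threshold,
                 epoch_window_ms = epoch_window_ms,
                 crop_window_ms = crop_window_ms),
            class = "preproc_config")
}

# Forward-backward filtering with odd-reflection padding at both ends
# (the scipy/MATLAB filtfilt convention), which suppresses the start-up
# transients plain filtfilt leaves on short segments with very low cutoffs.
zero_phase <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1L, 10000L)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filter of a continuous recording
#'
#' Applies cascaded Butterworth high-pass and low-pass sections with
#' forward-backward filtering (odd-reflection padded), so the passband is
#' preserved with zero phase shift and the DC component is removed.  The
#' channel mean is subtracted before high-pass filtering.
#'
#' @param raw an `"eeg_raw"` recording from [simulate_raw()] or
#'   [read_epochs()]-compatible sources.
#' @param cfg a [preproc_config()].
#' @return The recording with filtered `data`.
#' @export
bandpass_filter <- function(raw, cfg = preproc_config()) {
  nyq <- raw$sample_rate / 2
  if (cfg$lowpass_hz >= nyq)
    stop("lowpass cutoff (", cfg$lowpass_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  hp <- signal::butter(cfg$hp_order, cfg$highpass_hz / nyq, type = "high")
  lp <- signal::butter(cfg$lp_order, cfg$lowpass_hz / nyq, type = "low")
  raw$data <- t(apply(raw$data, 1, function(x)
    zero_phase(lp, zero_phase(hp, x - mean(x)))))
  raw
}

#' Detect noisy channels from their amplitude distribution
#'
#' Reimplements probability-based channel rejection: a kernel density
#' estimate is fitted to the pooled samples of all channels, each channel is
#' scored by the mean negative log-likelihood of its own samples under that
#' pooled distribution, and scores are z-scored across channels.  Channels
#' whose z-score exceeds `bad_channel_sd_threshold` (default 5 SD) are
#' returned.  Deterministic given the input.
#'
#' @inheritParams bandpass_filter
#' @param max_samples per-channel cap on samples entering the density
#'   estimate (evenly spaced subsampling; keeps the scan cheap).
#' @return Character vector of flagged channel labels (possibly empty).
#' @export
detect_bad_channels <- function(raw, cfg = preproc_config(),
                                max_samples = 20000L) {
  n_ch <- nrow(raw$data)
  if (n_ch < 8) stop("bad-channel detection needs >= 8 channels")
  n_s <- ncol(raw$data)
  keep <- if (n_s > max_samples)
    unique(as.integer(round(seq(1, n_s, length.out = max_samples))))
  else seq_len(n_s)
  x <- raw$data[, keep, drop = FALSE]
  dens <- density(as.numeric(x), n = 2048)
  loglik <- function(v) {
    d <- approx(dens$x, dens$y, xout = v, yleft = 0, yright = 0)$y
    mean(-log(pmax(d, 1e-12)))
  }
  nll <- apply(x, 1, loglik)
  z <- (nll - mean(nll)) / sd(nll)
  flagged <- raw$channels[z > cfg$bad_channel_sd_threshold]
  if (length(flagged) == n_ch)
    stop("all channels flagged as noisy; data unusable")
  flagged
}

#' Interpolate noisy channels from their neighbours
#'
#' Replaces each flagged channel by the inverse-squared-distance weighted
#' average of all good channels, using the electrode layout in
#' `raw$positions`.  Good channels are untouched, so the operation is
#' idempotent.
#'
#' @inheritParams bandpass_filter
#' @param bad labels of channels to interpolate.
#' @param positions channel-position matrix (defaults to `raw$positions`).
#' @return The recording with interpolated `data`.
#' @export
interpolate_channels <- function(raw, bad, positions = raw$positions) {
  if (length(bad) == 0) return(raw)
  if (is.null(positions)) stop("channel positions are required")
  if (!all(bad %in% raw$channels)) stop("unknown channel labels in 'bad'")
  good <- setdiff(raw$channels, bad)
  if (length(good) < 3) stop("need >= 3 good channels to interpolate")
  gi <- match(good, raw$channels)
  for (b in bad) {
    bi <- match(b, raw$channels)
    d2 <- rowSums((positions[gi, , drop = FALSE] -
                     matrix(positions[bi, ], length(gi), ncol(positions),
                            byrow = TRUE))^2)
    w <- 1 / pmax(d2, 1e-12)
    raw$data[bi, ] <- crossprod(raw$data[gi, , drop = FALSE], w)[, 1] / sum(w)
  }
  raw
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over channels, so the channel-mean
#' time series is identically zero.  Idempotent; channel differences are
#' unaffected.
#'
#' @inheritParams bandpass_filter
#' @return The re-referenced recording.
#' @export
rereference_average <- function(raw) {
  if (nrow(raw$data) < 2) stop("average reference needs >= 2 channels")
  raw$data <- sweep(raw$data, 2, colMeans(raw$data))
  raw
}

#' Downsample a continuous recording
#'
#' Anti-alias filtered resampling to `target_rate_hz`: the data are
#' zero-phase low-pass filtered at 90% of the new Nyquist frequency and
#' decimated (integer rate ratios, the usual EEG case) or polyphase
#' resampled otherwise.  Duration is preserved and event onset samples are
#' remapped to the new grid.
#'
#' @inheritParams bandpass_filter
#' @return The recording at the target rate.
#' @export
downsample <- function(raw, cfg = preproc_config()) {
  p <- cfg$target_rate_hz
  q <- raw$sample_rate
  if (p >= q) stop("target rate must be below the original rate")
  if (q %% p == 0) {
    f <- q %/% p
    aa <- signal::butter(6, 0.9 / f, type = "low")
    raw$data <- t(apply(raw$data, 1, function(x)
      zero_phase(aa, x)[seq(1, length(x), by = f)]))
    ratio <- 1 / f
  } else {
    g <- rate_gcd(round(p), round(q))
    raw$data <- t(apply(raw$data, 1, signal::resample,
                        p = round(p) / g, q = round(q) / g))
    ratio <- p / q
  }
  if (!is.null(raw$events$onset_sample))
    raw$events$onset_sample <-
      as.integer(round((raw$events$onset_sample - 1) * ratio)) + 1L
  raw$sample_rate <- cfg$target_rate_hz
  raw
}

rate_gcd <- function(a, b) if (b == 0) a else rate_gcd(b, a %% b)

#' Cut epochs, remove per-epoch linear trends, and crop
#'
#' Extracts one epoch per event over `cfg$epoch_window_ms` (onset-aligned
#' sample grid), removes each channel's least-squares linear trend within
#' the epoch, then crops to `cfg$crop_window_ms`.  Events whose window
#' extends past the recording edge are dropped with a warning; remaining
#' epochs keep their one-to-one correspondence with event rows.
#'
#' @inheritParams bandpass_filter
#' @param events event table with 1-based `onset_sample` (defaults to
#'   `raw$events`).
#' @return An [epoch_set()].
#' @export
epoch_and_detrend <- function(raw, events = raw$events,
                              cfg = preproc_config()) {
  dt <- 1000 / raw$sample_rate
  rel <- round(time_grid(cfg$epoch_window_ms, raw$sample_rate) / dt)
  n_s <- ncol(raw$data)
  ok <- events$onset_sample + min(rel) >= 1 &
    events$onset_sample + max(rel) <= n_s
  if (!all(ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  events <- events[ok, , drop = FALSE]
  times_full <- rel * dt
  tc <- times_full - mean(times_full)   # centred regressor for detrending
  keep <- times_full >= cfg$crop_window_ms[1] - 1e-9 &
    times_full <= cfg$crop_window_ms[2] + 1e-9
  n_ch <- nrow(raw$data)
  data <- array(0, dim = c(nrow(events), n_ch, sum(keep)))
  for (i in seq_len(nrow(events))) {
    ep <- raw$data[, events$onset_sample[i] + rel, drop = FALSE]
    slope <- (ep %*% tc) / sum(tc^2)
    ep <- ep - rowMeans(ep) - tcrossprod(slope[, 1], tc)
    data[i, , ] <- ep[, keep]
  }
  events$onset_sample <- NULL
  epoch_set(data, times_full[keep], raw$sample_rate, events,
            channels = raw$channels, positions = raw$positions)
}

#' Run the full preprocessing chain
#'
#' Fixed order: band-pass filter, noisy-channel detection and interpolation,
#' average re-reference, downsample, epoch + detrend + crop.
#'
#' @inheritParams bandpass_filter
#' @return An [epoch_set()] whose `bad_channels` records interpolated labels.
#' @export
preprocess_raw <- function(raw, cfg = preproc_config()) {
  raw <- bandpass_filter(raw, cfg)
  bad <- detect_bad_channels(raw, cfg)
  raw <- interpolate_channels(raw, bad)
  raw <- rereference_average(raw)
  raw <- downsample(raw, cfg)
  es <- epoch_and_detrend(raw, cfg = cfg)
  es$bad_channels <- bad
  es
}
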