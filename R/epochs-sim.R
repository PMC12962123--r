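#' Temporal envelope of an injected effect
#'
#' Evaluates the response envelope of a [class_effect()] on a time grid:
#' zero before onset, half-Gaussian rise between onset and peak (the rise
#' SD is one third of the onset-to-peak interval, so the envelope is
#' effectively zero at onset and 1 at the peak), a plateau at 1, then
#' exponential decay.
#'
#' @param effect a [class_effect()].
#' @param times_ms numeric vector of times (ms, 0 = stimulus onset).
#' @return Numeric vector of envelope values in \[0, 1\].
#' @export
effect_envelope <- function(effect, times_ms) {
  sigma <- (effect$peak_ms - effect$onset_ms) / 3
  plateau_end <- effect$peak_ms + effect$plateau_ms
  env <- numeric(length(times_ms))
  rise <- times_ms >= effect$onset_ms & times_ms <= effect$peak_ms
  env[rise] <- exp(-0.5 * ((times_ms[rise] - effect$peak_ms) / sigma)^2)
  flat <- times_ms > effect$peak_ms & times_ms <= plateau_end
  env[flat] <- 1
  tail <- times_ms > plateau_end
  env[tail] <- exp(-(times_ms[tail] - plateau_end) / effect$decay_tau_ms)
  env
}

# Onset-aligned sample grid covering a window (ms); sample 0 is at t = 0.
time_grid <- function(window_ms, sample_rate) {
  dt <- 1000 / sample_rate
  k <- seq.int(ceiling(window_ms[1] / dt - 1e-9),
               floor(window_ms[2] / dt + 1e-9))
  k * dt
}

#' Synthetic electrode layout
#'
#' Places `n` channels evenly on concentric rings of a unit disc, a stand-in
#' scalp layout used by distance-weighted channel interpolation.
#'
#' @param n number of channels.
#' @return An `n x 2` matrix of x/y coordinates, rownames = channel labels.
#' @export
channel_positions <- function(n) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  r <- 0.4 + 0.6 * ((seq_len(n) - 1) %% 4) / 3  # 4 interleaved rings
  pos <- cbind(x = r * cos(ang), y = r * sin(ang))
  rownames(pos) <- sprintf("ch%02d", seq_len(n))
  pos
}

# Fixed spatial patterns and per-stimulus signal matrices (channels x time)
# shared by the epoch and continuous-raw generators.  Patterns are unit-norm
# so effect amplitudes are expressed as multivariate signal norms.
stimulus_signals <- function(catalog, cfg, times_ms) {
  ch <- cfg$n_channels
  unit <- function(v) v / sqrt(sum(v^2))
  set.seed(stage_seed(cfg, 6L))
  img_pat <- apply(matrix(rnorm(ch * nrow(catalog)), ch), 2, unit)
  pat <- lapply(cfg$class_effect, function(eff) {
    set.seed(eff$spatial_pattern_seed)
    unit(rnorm(ch))
  })
  zs <- list(valence = as.numeric(scale(catalog$latent_valence)),
             sex = as.numeric(scale(catalog$latent_sex)))
  env_img <- effect_envelope(cfg$image_effect, times_ms)
  envs <- lapply(cfg$class_effect, effect_envelope, times_ms = times_ms)
  sig <- array(0, dim = c(ch, length(times_ms), nrow(catalog)))
  for (s in seq_len(nrow(catalog))) {
    m <- tcrossprod(img_pat[, s], cfg$image_effect_amplitude * env_img)
    for (a in names(cfg$class_effect)) {
      amp <- cfg$class_effect[[a]]$amplitude
      if (amp != 0)
        m <- m + tcrossprod(pat[[a]], amp * zs[[a]][s] * envs[[a]])
    }
    sig[, , s] <- m
  }
  list(signals = sig, image_patterns = img_pat, class_patterns = pat,
       latent_z = zs)
}

# Spatial mixing matrix that correlates channel noise.
noise_mixing <- function(cfg) {
  ch <- cfg$n_channels
  set.seed(stage_seed(cfg, 7L))
  diag(ch) + cfg$noise$channel_cov_mixing *
    matrix(rnorm(ch * ch), ch, ch) / sqrt(ch)
}

#' Construct an epoched-EEG container
#'
#' @param data numeric array `trials x channels x timepoints`.
#' @param times time vector (ms), strictly increasing and uniformly spaced.
#' @param sample_rate sampling rate (Hz).
#' @param events `data.frame` with one row per trial (columns `trial`,
#'   `sequence`, `block`, `stimulus_id`).
#' @param channels channel labels (default `ch01`, ...).
#' @param positions optional channel-position matrix.
#' @param bad_channels labels of channels flagged as noisy.
#' @return A list of class `"epoch_set"`.
#' @export
epoch_set <- function(data, times, sample_rate, events,
                      channels = sprintf("ch%02d", seq_len(dim(data)[2])),
                      positions = NULL, bad_channels = character(0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times),
            dim(data)[2] == length(channels))
  if (nrow(events) != dim(data)[1])
    stop("events rows (", nrow(events), ") must equal trials (",
         dim(data)[1], ")")
  dts <- diff(times)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6)
    stop("times must be strictly increasing and uniformly spaced")
  structure(list(data = data, times = times, sample_rate = sample_rate,
                 channels = channels, events = events,
                 positions = positions, bad_channels = bad_channels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<epoch_set> %d trials x %d channels x %d timepoints ",
                     "(%.4g..%.4g ms @ %g Hz)\n"),
              d[1], d[2], d[3], min(x$times), max(x$times), x$sample_rate))
  invisible(x)
}

#' Simulate epoched EEG with known ground truth
#'
#' Generates one subject's epochs directly on the epoch grid.  Each trial is
#' spatially mixed Gaussian noise plus, from stimulus onset, (i) a fixed
#' image-specific channel pattern under a generic evoked envelope and (ii)
#' one pattern per rated attribute, scaled by the stimulus' standardised
#' latent attribute value and by that attribute's [effect_envelope()].
#' Pre-stimulus samples carry noise only.  Attribute signals scale
#' continuously with the latent values, so class decoding (extreme groups)
#' and RSA (rating-gap structure) both have recoverable ground truth.
#'
#' @param catalog a [stimulus_catalog()].
#' @param schedule a [build_schedule()] event table.
#' @param cfg a [sim_config()].
#' @param subject_seed integer seed for this subject's noise draw.
#' @return An [epoch_set()] with attribute `"ground_truth"`: a list holding
#'   the true onset/peak times per attribute, the spatial patterns, and the
#'   standardised latent values.
#' @export
simulate_epochs <- function(catalog, schedule, cfg, subject_seed = 1L) {
  if (!all(schedule$stimulus_id %in% catalog$stimulus_id))
    stop("schedule references stimuli missing from the catalog")
  times <- time_grid(cfg$epoch_window, cfg$sample_rate)
  ss <- stimulus_signals(catalog, cfg, times)
  A <- noise_mixing(cfg)
  n_tr <- nrow(schedule)
  ch <- cfg$n_channels
  nt <- length(times)
  set.seed(as.integer(subject_seed))
  noise <- cfg$noise$sd * (A %*% matrix(rnorm(ch * n_tr * nt), ch))
  dim(noise) <- c(ch, n_tr, nt)
  stim_idx <- match(schedule$stimulus_id, catalog$stimulus_id)
  data <- array(0, dim = c(n_tr, ch, nt))
  for (i in seq_len(n_tr))
    data[i, , ] <- noise[, i, ] + ss$signals[, , stim_idx[i]]
  gt <- list(
    onset_ms = vapply(cfg$class_effect, `[[`, numeric(1), "onset_ms"),
    peak_ms = vapply(cfg$class_effect, `[[`, numeric(1), "peak_ms"),
    class_patterns = ss$class_patterns,
    image_patterns = ss$image_patterns,
    latent_z = ss$latent_z,
    subject_seed = as.integer(subject_seed))
  es <- epoch_set(data, times, cfg$sample_rate, schedule,
                  positions = channel_positions(ch))
  attr(es, "ground_truth") <- gt
  es
}

#' Simulate a continuous multichannel recording
#'
#' Generates one subject's raw recording at a high sampling rate (1024 Hz by
#' default) with the same signal model as [simulate_epochs()]: stimuli are
#' presented every `soa_ms`, each onset injecting its channels-by-time
#' signal into spatially mixed continuous noise.  Intended as input for the
#' preprocessing chain ([bandpass_filter()] through [epoch_and_detrend()]).
#'
#' @inheritParams simulate_epochs
#' @param raw_sample_rate recording rate (Hz).
#' @param soa_ms stimulus-onset asynchrony (ms between trial onsets).
#' @param pad_ms quiet padding before the first and after the last trial.
#' @return A list of class `"eeg_raw"`: `data` (channels x samples matrix),
#'   `sample_rate`, `channels`, `positions`, `events` (schedule plus an
#'   `onset_sample` column, 1-based).
#' @export
simulate_raw <- function(catalog, schedule, cfg, subject_seed = 1L,
                         raw_sample_rate = 1024, soa_ms = 8000 / 30,
                         pad_ms = 800) {
  dt <- 1000 / raw_sample_rate
  n_tr <- nrow(schedule)
  n_samp <- ceiling((2 * pad_ms + n_tr * soa_ms) / dt)
  ch <- cfg$n_channels
  sig_times <- seq(0, min(4 * soa_ms, 1200), by = dt)
  ss <- stimulus_signals(catalog, cfg, sig_times)
  A <- noise_mixing(cfg)
  set.seed(as.integer(subject_seed) + 500000L)
  data <- cfg$noise$sd * (A %*% matrix(rnorm(ch * n_samp), ch))
  onset <- 1L + as.integer(round((pad_ms + (seq_len(n_tr) - 1) * soa_ms) / dt))
  stim_idx <- match(schedule$stimulus_id, catalog$stimulus_id)
  len <- length(sig_times)
  for (i in seq_len(n_tr)) {
    span <- onset[i]:min(onset[i] + len - 1L, n_samp)
    data[, span] <- data[, span] +
      ss$signals[, seq_along(span), stim_idx[i]]
  }
  events <- schedule
  events$onset_sample <- onset
  structure(list(data = data, sample_rate = raw_sample_rate,
                 channels = sprintf("ch%02d", seq_len(ch)),
                 positions = channel_positions(ch), events = events),
            class = "eeg_raw")
}
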