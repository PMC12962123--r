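#' Temporal response profile of an injected class effect
#'
#' Describes the time course of a simulated attribute-dependent evoked
#' response: zero before `onset_ms`, a half-Gaussian rise from `onset_ms` to
#' `peak_ms`, a plateau of `plateau_ms`, then an exponential decay with time
#' constant `decay_tau_ms`.  Onset and peak are therefore distinct,
#' recoverable quantities.
#'
#' @param onset_ms time (ms after stimulus onset) at which the effect starts
#'   rising; must be `>= 0` and `< peak_ms`.
#' @param peak_ms time (ms) at which the envelope reaches 1.
#' @param amplitude scalar multiplier applied to the spatial pattern.
#' @param spatial_pattern_seed integer seed for the fixed channel pattern
#'   carrying this effect.
#' @param plateau_ms duration (ms) the envelope stays at 1 after the peak.
#' @param decay_tau_ms exponential decay time constant (ms) after the plateau.
#' @return A list of class `"class_effect"`.
#' @export
class_effect <- function(onset_ms, peak_ms, amplitude = 1,
                         spatial_pattern_seed = 1L,
                         plateau_ms = 40, decay_tau_ms = 80) {
  if (onset_ms < 0) stop("class effect onset must be >= 0 ms")
  if (onset_ms >= peak_ms) stop("class effect onset must precede its peak")
  structure(list(onset_ms = onset_ms, peak_ms = peak_ms,
                 amplitude = amplitude,
                 spatial_pattern_seed = as.integer(spatial_pattern_seed),
                 plateau_ms = plateau_ms, decay_tau_ms = decay_tau_ms),
            class = "class_effect")
}

#' Configuration for the synthetic face-perception dataset
#'
#' Bundles every parameter of the generator: the stimulus catalogue, the two
#' rating experiments (9-point valence and perceived-sex scales), the rapid
#' serial presentation schedule, and the epoched EEG signal model.  Defaults
#' mirror the emulated study design: 900 stimuli (840 human faces, 60
#' non-face images), 60 valence raters and 72 sex raters each rating 300
#' stimuli, 12 presentations of each stimulus arranged as 72 sequences of
#' 150 trials with every 6-sequence block containing each stimulus once,
#' 64 channels at 256 Hz with epochs from -100 to 1000 ms.
#'
#' @param n_stimuli total number of stimuli.
#' @param n_human number of stimuli in the human-face class; the remainder
#'   are the non-face (pareidolia) class.
#' @param n_raters_valence,n_raters_sex rater counts per attribute.
#' @param ratings_per_rater stimuli rated by each rater (random subset).
#' @param latent_correlation correlation between the latent valence and
#'   masculinity dimensions, in (-1, 1).  Slightly negative by default:
#'   more masculine faces carry slightly more negative expressions.
#' @param rater_noise_sd SD of rater noise in rating units before
#'   discretisation.
#' @param rating_scale_sd slope of the affine map from the standard-normal
#'   latent to the 9-point scale (ratings = 5 + slope * latent + noise).
#' @param n_subjects number of simulated EEG participants.
#' @param n_channels number of EEG channels.
#' @param sample_rate sampling rate in Hz of the epoched data.
#' @param epoch_window `c(start_ms, end_ms)` of the epochs, with 0 at
#'   stimulus onset; start must be negative and end positive.
#' @param trials_per_sequence,sequences_per_block presentation schedule;
#'   `trials_per_sequence * sequences_per_block` must equal `n_stimuli`.
#' @param n_blocks number of blocks, i.e. presentations of each stimulus.
#' @param class_effect named list with elements `valence` and `sex`, each a
#'   [class_effect()], describing the injected attribute signals.
#' @param image_effect a [class_effect()] describing the time course of the
#'   image-specific (stimulus-identity) response.
#' @param image_effect_amplitude amplitude of the image-specific pattern.
#' @param image_size side length (pixels) of the square stimulus images.
#' @param image_mean,image_sd mean and SD of pixel intensities (0-255).
#' @param image_class_offset added to the mean intensity of non-face images.
#' @param image_lowfreq_amplitude amplitude of a low-spatial-frequency
#'   sinusoidal component added to non-face images.
#' @param image_lowfreq_cycles cycles per image of that component.
#' @param noise list with `channel_cov_mixing` (strength of the random
#'   spatial mixing that correlates channel noise, >= 0) and `sd` (noise
#'   standard deviation per channel).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_stimuli = 900L, n_human = 840L,
                       n_raters_valence = 60L, n_raters_sex = 72L,
                       ratings_per_rater = 300L,
                       latent_correlation = -0.1, rater_noise_sd = 1,
                       rating_scale_sd = 2,
                       n_subjects = 40L, n_channels = 64L,
                       sample_rate = 256, epoch_window = c(-100, 1000),
                       trials_per_sequence = 150L, sequences_per_block = 6L,
                       n_blocks = 12L,
                       class_effect = list(
                         valence = eegmvpa::class_effect(80, 120, 1, 11L),
                         sex = eegmvpa::class_effect(110, 160, 1, 22L)),
                       image_effect = eegmvpa::class_effect(60, 110, 1, 33L),
                       image_effect_amplitude = 1,
                       image_size = 64L, image_mean = 128, image_sd = 30,
                       image_class_offset = 0,
                       image_lowfreq_amplitude = 0,
                       image_lowfreq_cycles = 2,
                       noise = list(channel_cov_mixing = 0.5, sd = 1),
                       seed = 1L) {
  counts <- c(n_stimuli, n_human, n_raters_valence, n_raters_sex,
              ratings_per_rater, n_subjects, n_channels,
              trials_per_sequence, sequences_per_block, n_blocks)
  if (any(counts < 1)) stop("all design counts must be >= 1")
  if (n_human > n_stimuli) stop("n_human cannot exceed n_stimuli")
  if (abs(latent_correlation) >= 1)
    stop("latent_correlation must lie in (-1, 1)")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (!(epoch_window[1] < 0 && 0 < epoch_window[2]))
    stop("epoch_window must straddle 0 (start < 0 < end)")
  if (!all(c("valence", "sex") %in% names(class_effect)))
    stop("class_effect must have elements 'valence' and 'sex'")
  cfg <- list(n_stimuli = as.integer(n_stimuli),
              n_human = as.integer(n_human),
              n_raters_valence = as.integer(n_raters_valence),
              n_raters_sex = as.integer(n_raters_sex),
              ratings_per_rater = as.integer(ratings_per_rater),
              latent_correlation = latent_correlation,
              rater_noise_sd = rater_noise_sd,
              rating_scale_sd = rating_scale_sd,
              n_subjects = as.integer(n_subjects),
              n_channels = as.integer(n_channels),
              sample_rate = sample_rate,
              epoch_window = epoch_window,
              trials_per_sequence = as.integer(trials_per_sequence),
              sequences_per_block = as.integer(sequences_per_block),
              n_blocks = as.integer(n_blocks),
              class_effect = class_effect,
              image_effect = image_effect,
              image_effect_amplitude = image_effect_amplitude,
              image_size = as.integer(image_size),
              image_mean = image_mean, image_sd = image_sd,
              image_class_offset = image_class_offset,
              image_lowfreq_amplitude = image_lowfreq_amplitude,
              image_lowfreq_cycles = image_lowfreq_cycles,
              noise = noise,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Derive a reproducible stage seed from the master seed.  Stage offsets are
# fixed constants so that changing one stage's draw never perturbs another.
stage_seed <- function(cfg, offset) {
  as.integer((as.numeric(cfg$seed) * 1009 + offset) %% .Machine$integer.max)
}

#' Stimulus catalogue with latent attribute values
#'
#' Creates the per-stimulus ground truth: a category label (`human` for the
#' face class, `nonhuman` for the pareidolia/non-face class) and a pair of
#' latent attribute values (valence and masculinity) drawn from a bivariate
#' standard normal with correlation `cfg$latent_correlation`.  The latent
#' values drive both the simulated ratings and the injected EEG signals.
#'
#' @param cfg a [sim_config()].
#' @return A `data.frame` with columns `stimulus_id` (0-based), `category`
#'   (factor `human`/`nonhuman`), `latent_valence`, `latent_sex`.
#' @export
stimulus_catalog <- function(cfg) {
  set.seed(stage_seed(cfg, 1L))
  n <- cfg$n_stimuli
  rho <- cfg$latent_correlation
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(
    stimulus_id = seq_len(n) - 1L,
    category = factor(rep(c("human", "nonhuman"),
                          c(cfg$n_human, n - cfg$n_human)),
                      levels = c("human", "nonhuman")),
    latent_valence = z1,
    latent_sex = z2)
}
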