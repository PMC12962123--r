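# Shared builders for desk-scale simulated datasets.  Sizes are kept small
# so the whole suite runs quickly on one CPU; the generative conditions
# (block structure, 12 repeats, envelope shapes) match the full design.

tiny_cfg <- function(seed = 7L, amplitude = 8, image_amp = 0.5,
                     noise_sd = 1, n_subjects = 3L, n_blocks = 4L,
                     sample_rate = 64, window = c(-100, 400)) {
  sim_config(
    n_stimuli = 12L, n_human = 10L,
    n_raters_valence = 8L, n_raters_sex = 8L, ratings_per_rater = 6L,
    n_subjects = n_subjects, n_channels = 16L,
    sample_rate = sample_rate, epoch_window = window,
    trials_per_sequence = 6L, sequences_per_block = 2L,
    n_blocks = n_blocks, seed = seed,
    class_effect = list(
      valence = class_effect(80, 120, amplitude = amplitude,
                             spatial_pattern_seed = 11L),
      sex = class_effect(110, 160, amplitude = amplitude,
                         spatial_pattern_seed = 22L)),
    image_effect = class_effect(60, 110, 1, 33L),
    image_effect_amplitude = image_amp,
    noise = list(channel_cov_mixing = 0.3, sd = noise_sd))
}

tiny_epochs <- function(cfg = tiny_cfg(), subject_seed = 1L,
                        schedule_seed = 1L) {
  catalog <- stimulus_catalog(cfg)
  schedule <- build_schedule(cfg, seed = schedule_seed)
  simulate_epochs(catalog, schedule, cfg, subject_seed = subject_seed)
}

# Independent fixed-grid Simpson-rule oracle for the JZS interval Bayes
# factor; shares no quadrature code with the package implementation.
oracle_jzs_marginal <- function(tstat, n, r, lo, hi, m = 200001) {
  lo2 <- max(lo, -60); hi2 <- min(hi, 60)
  x <- seq(lo2, hi2, length.out = m)
  h <- x[2] - x[1]
  f <- dt(tstat, df = n - 1, ncp = sqrt(n) * x) * dcauchy(x, scale = r)
  w <- c(1, rep(c(4, 2), (m - 3) / 2), 4, 1)
  (h / 3) * sum(w * f) /
    (pcauchy(hi, scale = r) - pcauchy(lo, scale = r))
}

oracle_jzs_bf <- function(tstat, n, cfg) {
  r <- cfg$prior_scale
  lo <- cfg$null_interval[1]; hi <- cfg$null_interval[2]
  m_null <- if (lo == hi) dt(tstat, n - 1, ncp = sqrt(n) * lo)
  else oracle_jzs_marginal(tstat, n, r, lo, hi)
  m_alt <- if (cfg$direction == "above_chance_one_sided") {
    oracle_jzs_marginal(tstat, n, r, hi, Inf)
  } else {
    ml <- pcauchy(lo, scale = r)
    mu <- pcauchy(hi, scale = r, lower.tail = FALSE)
    (oracle_jzs_marginal(tstat, n, r, -Inf, lo) * ml +
       oracle_jzs_marginal(tstat, n, r, hi, Inf) * mu) / (ml + mu)
  }
  m_alt / m_null
}
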