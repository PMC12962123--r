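test_that("catalog matches configured class counts and correlation sign", {
  cfg <- sim_config(seed = 3L)
  cat_ <- stimulus_catalog(cfg)
  expect_equal(nrow(cat_), 900L)
  expect_false(any(duplicated(cat_$stimulus_id)))
  expect_equal(as.integer(table(cat_$category)), c(840L, 60L))
  expect_lt(cor(cat_$latent_valence, cat_$latent_sex), 0)
  # identical seed -> bit-identical catalogue
  expect_identical(cat_, stimulus_catalog(sim_config(seed = 3L)))
})

test_that("rating tables cover every stimulus with the configured row count", {
  cfg <- sim_config(seed = 5L)
  cat_ <- stimulus_catalog(cfg)
  tab <- simulate_ratings(cat_, cfg, "valence")
  expect_equal(nrow(tab), 60L * 300L)
  expect_setequal(unique(tab$stimulus_id), cat_$stimulus_id)
  expect_true(all(tab$rating %in% 1:9))
  expect_equal(as.integer(table(tab$rater_id)), rep(300L, 60L))
  # impossible coverage fails loudly
  bad <- sim_config(n_stimuli = 12L, n_human = 10L, n_raters_valence = 2L,
                    ratings_per_rater = 4L, trials_per_sequence = 6L,
                    sequences_per_block = 2L)
  expect_error(simulate_ratings(stimulus_catalog(bad), bad, "valence"),
               "coverage")
})

test_that("noiseless mean ratings are a monotone transform of the latents", {
  cfg <- tiny_cfg()
  cfg$rater_noise_sd <- 0
  cfg$n_raters_valence <- 12L
  cfg$ratings_per_rater <- 12L
  cat_ <- stimulus_catalog(cfg)
  scores <- aggregate_ratings(simulate_ratings(cat_, cfg, "valence"))
  ord <- order(cat_$latent_valence)
  expect_true(all(diff(scores$mean_rating[ord]) >= 0))
})

test_that("mean valence and mean sex ratings correlate negatively as generated", {
  cfg <- sim_config(seed = 1L)   # latent correlation -0.1, full rater counts
  cat_ <- stimulus_catalog(cfg)
  sv <- aggregate_ratings(simulate_ratings(cat_, cfg, "valence"))
  ss <- aggregate_ratings(simulate_ratings(cat_, cfg, "sex"))
  res <- correlate_attributes(sv, ss)
  expect_lt(res$rho, 0)
  expect_equal(res$n, 900L)
})

test_that("schedule has the full-design shape and per-block balance", {
  sch <- build_schedule(sim_config())
  expect_equal(nrow(sch), 10800L)
  expect_equal(max(sch$block), 12L)
  expect_equal(max(sch$sequence), 72L)
  expect_true(all(table(sch$stimulus_id, sch$block) == 1))
})

test_that("miniature schedules balance blocks and reject inconsistent designs", {
  cfg <- sim_config(n_stimuli = 6L, n_human = 5L, trials_per_sequence = 3L,
                    sequences_per_block = 2L, n_blocks = 2L)
  sch <- build_schedule(cfg)
  expect_equal(nrow(sch), 12L)
  expect_equal(as.integer(table(sch$stimulus_id)), rep(2L, 6L))
  expect_true(all(table(sch$stimulus_id, sch$block) == 1))
  bad <- cfg
  bad$trials_per_sequence <- 4L
  expect_error(build_schedule(bad), "must equal n_stimuli")
})

test_that("epoch simulation is seeded-reproducible with silent pre-stimulus", {
  cfg <- tiny_cfg(amplitude = 10, image_amp = 4)
  ep1 <- tiny_epochs(cfg, subject_seed = 9L)
  ep2 <- tiny_epochs(cfg, subject_seed = 9L)
  expect_identical(ep1$data, ep2$data)
  expect_equal(dim(ep1$data), c(48L, 16L, length(ep1$times)))
  # pre-stimulus samples carry zero injected signal: averaging the repeats
  # of one stimulus leaves only noise before onset, but its deterministic
  # evoked pattern after onset.  (Averaging over all stimuli would cancel
  # the signal too, because latent values and patterns are zero-mean.)
  gt <- attr(ep1, "ground_truth")
  expect_equal(gt$onset_ms, c(valence = 80, sex = 110))
  s_star <- which.max(abs(gt$latent_z$valence))
  trials <- which(ep1$events$stimulus_id ==
                    stimulus_catalog(cfg)$stimulus_id[s_star])
  erp <- apply(ep1$data[trials, , , drop = FALSE], c(2, 3), mean)
  pre_mean <- mean(abs(erp[, ep1$times < 0]))
  post_mean <- mean(abs(erp[, ep1$times > 90 & ep1$times < 200]))
  expect_lt(pre_mean, 0.8)          # ~ noise / sqrt(n repeats) scale
  expect_gt(post_mean, 2 * pre_mean)
})

test_that("degenerate effect timings are rejected", {
  expect_error(class_effect(120, 80), "precede")
  expect_error(class_effect(-10, 80), ">= 0")
})

test_that("simulated images realise the configured class differences", {
  cfg <- tiny_cfg()
  cfg$image_size <- 48L
  cfg$image_sd <- 10
  cfg$image_class_offset <- 25
  cfg$image_lowfreq_amplitude <- 40
  cat_ <- stimulus_catalog(cfg)
  dir <- withr::local_tempdir()
  manifest <- simulate_images(cat_, cfg, dir)
  stats <- image_stats(manifest$path, manifest$stimulus_id)
  human <- manifest$category == "human"
  # luminance offset round-trips through the 8-bit files
  expect_equal(mean(stats$luminance[!human]) - mean(stats$luminance[human]),
               25, tolerance = 0.15)
  # the added low-frequency grating elevates the low band of that class
  expect_gt(mean(stats$low_sf[!human]), 1.5 * mean(stats$low_sf[human]))
  # constant-intensity image -> zero contrast
  flat <- cfg
  flat$image_sd <- 0
  flat$image_class_offset <- 0
  flat$image_lowfreq_amplitude <- 0
  m2 <- simulate_images(stimulus_catalog(flat)[1:2, ], flat, dir)
  s2 <- basic_stats(read_image(m2$path[1]))
  expect_equal(s2$contrast, 0)
  expect_equal(s2$luminance, 128, tolerance = 0.5)
  # non-square size rejected
  bad <- cfg
  bad$image_size <- 16L
  expect_error(simulate_images(cat_, bad, dir), ">= 32")
})

test_that("continuous recordings place each trial's signal at its onset", {
  cfg <- tiny_cfg(amplitude = 0, image_amp = 0, noise_sd = 0.001,
                  n_blocks = 4L)
  cfg$class_effect$valence$amplitude <- 10
  cat_ <- stimulus_catalog(cfg)
  sch <- build_schedule(cfg, seed = 2L)
  raw <- simulate_raw(cat_, sch, cfg, subject_seed = 3L,
                      raw_sample_rate = 512)
  expect_equal(nrow(raw$data), 16L)
  expect_equal(nrow(raw$events), nrow(sch))
  # around a strong-latent trial the signal power rises after onset
  z <- as.numeric(scale(cat_$latent_valence))
  tr <- which.max(abs(z[match(sch$stimulus_id, cat_$stimulus_id)]))
  on <- raw$events$onset_sample[tr]
  dt <- 1000 / raw$sample_rate
  pre <- raw$data[, on - round(80 / dt):1]
  post <- raw$data[, on + round(100 / dt) + 0:round(60 / dt)]
  expect_gt(mean(post^2), 10 * mean(pre^2))
})
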