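fake_raw <- function(data, sample_rate = 1024) {
  structure(list(data = data, sample_rate = sample_rate,
                 channels = sprintf("ch%02d", seq_len(nrow(data))),
                 positions = channel_positions(nrow(data)),
                 events = NULL),
            class = "eeg_raw")
}

test_that("band-pass removes DC, keeps the passband, kills high frequencies", {
  fs <- 1024
  t <- seq(0, 4, by = 1 / fs)
  sig10 <- sin(2 * pi * 10 * t)
  sig150 <- sin(2 * pi * 150 * t)
  raw <- fake_raw(rbind(sig10 + 7, sig150, rnorm(length(t))), fs)
  filt <- bandpass_filter(raw, preproc_config())
  mid <- seq(fs, 3 * fs)  # avoid forward-backward edge transients
  expect_lt(abs(mean(filt$data[1, mid])), 0.02)            # DC gone
  amp <- function(x) sqrt(2 * mean(x^2))
  expect_equal(amp(filt$data[1, mid]), 1, tolerance = 0.01)  # 10 Hz kept
  expect_lt(amp(filt$data[2, mid]), 0.1)                     # 150 Hz crushed
  expect_error(bandpass_filter(fake_raw(raw$data, 128), preproc_config()),
               "Nyquist")
})

test_that("probability-based channel scan flags only planted outliers", {
  set.seed(21)
  data <- matrix(rnorm(64 * 4000), 64)
  raw <- fake_raw(data, 256)
  expect_length(detect_bad_channels(raw), 0)
  raw$data[17, ] <- 100 * rnorm(4000)
  expect_identical(detect_bad_channels(raw), "ch17")
  # an unreachable threshold flags nothing
  lax <- preproc_config(bad_channel_sd_threshold = 1e6)
  expect_length(detect_bad_channels(raw, lax), 0)
  expect_error(detect_bad_channels(fake_raw(data[1:4, ], 256)), ">= 8")
})

test_that("interpolation reconstructs from neighbours and is idempotent", {
  set.seed(22)
  n_ch <- 64
  raw <- fake_raw(matrix(rep(rnorm(3000), each = n_ch), n_ch), 256)
  raw$data[5, ] <- raw$data[5, ] * 100     # identical neighbours, one outlier
  fixed <- interpolate_channels(raw, "ch05")
  expect_equal(fixed$data[5, ], fixed$data[6, ], tolerance = 1e-10)
  expect_identical(fixed$data, interpolate_channels(fixed, "ch05")$data)
  # round-trip: a planted outlier passes the scan after interpolation
  noisy <- fake_raw(matrix(rnorm(n_ch * 4000), n_ch), 256)
  noisy$data[9, ] <- 100 * rnorm(4000)
  cleaned <- interpolate_channels(noisy, detect_bad_channels(noisy))
  expect_length(detect_bad_channels(cleaned), 0)
  no_pos <- noisy
  no_pos$positions <- NULL
  expect_error(interpolate_channels(no_pos, "ch09"), "positions")
})

test_that("average reference zeroes the channel mean and is a projection", {
  set.seed(23)
  raw <- fake_raw(matrix(rnorm(16 * 500), 16), 256)
  ref <- rereference_average(raw)
  expect_lt(max(abs(colMeans(ref$data))), 1e-12)
  expect_equal(rereference_average(ref)$data, ref$data)
  expect_equal(ref$data[1, ] - ref$data[2, ], raw$data[1, ] - raw$data[2, ])
})

test_that("downsampling preserves duration, amplitude and the 256 Hz grid", {
  fs <- 1024
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  raw <- fake_raw(rbind(sin(2 * pi * 8 * t), cos(2 * pi * 5 * t)), fs)
  down <- downsample(raw, preproc_config(target_rate_hz = 256))
  expect_equal(ncol(down$data), 256L)
  expect_equal(down$sample_rate, 256)
  expect_equal(1000 / down$sample_rate, 3.90625)
  mid <- 40:215
  expect_equal(sqrt(2 * mean(down$data[1, mid]^2)), 1, tolerance = 0.02)
  expect_error(downsample(down, preproc_config(target_rate_hz = 512)),
               "below the original")
})

test_that("epoching detrends ramps, crops to the grid, and keeps labels", {
  fs <- 256
  n_ch <- 4
  n_s <- 2000
  data <- matrix(rep(seq_len(n_s), each = n_ch) * 0.01, n_ch)  # pure ramp
  raw <- fake_raw(data, fs)
  raw$events <- data.frame(trial = 1:2, sequence = 1L, block = 1L,
                           stimulus_id = c(4L, 9L),
                           onset_sample = c(400L, 1200L))
  cfg <- preproc_config(epoch_window_ms = c(-533, 1067),
                        crop_window_ms = c(-100, 1000))
  es <- epoch_and_detrend(raw, cfg = cfg)
  expect_equal(dim(es$data), c(2L, 4L, 282L))   # -100..1000 ms at 256 Hz
  expect_equal(es$events$stimulus_id, c(4L, 9L))
  expect_lt(max(abs(es$data)), 1e-9)            # linear trend fully removed
  expect_equal(es$times[which(es$times == 0)], 0)
  # events without full window support are dropped with a warning
  raw$events$onset_sample[2] <- n_s - 10L
  expect_warning(es2 <- epoch_and_detrend(raw, cfg = cfg), "dropped")
  expect_equal(dim(es2$data)[1], 1L)
})

test_that("full chain turns a continuous simulation into clean epochs", {
  cfg <- tiny_cfg(amplitude = 6, image_amp = 1, n_blocks = 3L)
  cat_ <- stimulus_catalog(cfg)
  sch <- build_schedule(cfg, seed = 4L)
  raw <- simulate_raw(cat_, sch, cfg, subject_seed = 5L,
                      raw_sample_rate = 512, pad_ms = 900)
  pp <- preproc_config(target_rate_hz = 128, lowpass_hz = 100,
                       epoch_window_ms = c(-250, 500),
                       crop_window_ms = c(-100, 400))
  es <- preprocess_raw(raw, pp)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$data)[1], nrow(sch))
  expect_equal(es$sample_rate, 128)
  expect_false(any(!is.finite(es$data)))
  # re-referencing holds within every epoch
  expect_lt(max(abs(apply(es$data, c(1, 3), mean))), 1e-9)
})
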