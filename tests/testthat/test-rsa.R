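test_that("condensed/square round trip is lossless and lengths check out", {
  set.seed(61)
  v <- runif(10)
  r <- rdm(v, ids = letters[1:5])
  expect_equal(rdm_condense(rdm_square(r), metric = r$metric)$condensed, v)
  expect_error(rdm(runif(9), letters[1:5]), "does not match")
  # 840 of 900 conditions -> 352,380 pairs
  expect_equal(840 * 839 / 2, 352380)
  sub <- rdm_subset(rdm(runif(45), ids = 0:9), keep_ids = 0:5)
  expect_length(sub$condensed, 15L)
})

test_that("correlation-distance RDM is zero for identical patterns", {
  cfg <- tiny_cfg(amplitude = 0, image_amp = 0)
  ep <- tiny_epochs(cfg)
  # overwrite data so every condition shares one pattern at timepoint 1
  pat <- rnorm(dim(ep$data)[2])
  for (i in seq_len(dim(ep$data)[1])) ep$data[i, , 1] <- pat
  r <- neural_rdm(ep, 1, metric = "corr_distance")
  expect_equal(max(abs(r$condensed)), 0, tolerance = 1e-10)
})

test_that("decoding-metric RDM reuses pairwise accuracies and is ~0.5 on null", {
  cfg <- tiny_cfg(amplitude = 0, image_amp = 0)
  ep <- tiny_epochs(cfg)
  pw <- pairwise_image_decoding(ep)
  r <- neural_rdm(ep, 3, metric = "cv_decoding", pairwise = pw)
  expect_equal(r$condensed, pw$pair_accuracy[, 3])
  # chance level holds for the whole series (single timepoints fluctuate
  # because pairs sharing a stimulus share trials)
  expect_equal(mean(pw$pair_accuracy), 0.5, tolerance = 0.03)
  expect_error(neural_rdm(ep, 3, metric = "cv_decoding"), "store_pairs")
})

test_that("RSA timecourse recovers a planted behavioural geometry", {
  cfg <- tiny_cfg()
  ep <- tiny_epochs(cfg)
  ser <- neural_rdm_series(ep, metric = "corr_distance")
  # behavioural RDM equal to a neural RDM -> rho 1 at that timepoint
  behav <- rdm(ser$condensed[, 5], ser$ids, metric = "abs_rating_diff")
  rsa <- rsa_timecourse(list(ser), behav)
  expect_equal(rsa$rho[5], 1)
  # monotone transform of either RDM leaves Spearman untouched
  behav2 <- behav
  behav2$condensed <- behav$condensed^3
  expect_equal(rsa_timecourse(list(ser), behav2)$rho, rsa$rho)
  # behavioural RDM independent of null neural RDMs -> mean rho ~ 0
  null_ser <- neural_rdm_series(tiny_epochs(tiny_cfg(amplitude = 0,
                                                     image_amp = 0)),
                                metric = "corr_distance")
  set.seed(62)
  rand_behav <- rdm(runif(length(behav$condensed)), behav$ids)
  rsa_null <- rsa_timecourse(list(null_ser), rand_behav)
  expect_lt(abs(mean(rsa_null$rho)), 0.1)
  # condition mismatch is reported
  wrong <- rdm_subset(behav, behav$ids[-1])
  expect_error(rsa_timecourse(list(ser), wrong), "mismatch")
})

test_that("subset RSA equals full RSA when keeping all conditions", {
  cfg <- tiny_cfg()
  ep <- tiny_epochs(cfg)
  ser <- neural_rdm_series(ep, metric = "corr_distance")
  behav <- rdm(seq_along(ser$condensed[, 1]), ser$ids)
  full <- rsa_timecourse(list(ser), behav)
  same <- rsa_timecourse(list(ser), behav, keep_ids = ser$ids)
  expect_equal(same$rho, full$rho)
  sub <- rsa_timecourse(list(ser), behav, keep_ids = ser$ids[1:8])
  expect_equal(sub$subset, "subset")
  expect_error(rsa_timecourse(list(ser), behav, keep_ids = ser$ids[1]),
               ">= 2")
})

test_that("human-only subset isolates signal carried by human faces", {
  # non-face conditions carry a scrambled (independent) sex signal: the
  # human-only RSA should exceed the all-stimuli RSA in the injected window
  cfg <- tiny_cfg(amplitude = 5, image_amp = 0, n_subjects = 4L)
  cat_ <- stimulus_catalog(cfg)
  sers <- lapply(1:4, function(s) {
    ep <- simulate_epochs(cat_, build_schedule(cfg, seed = s), cfg, s)
    gt <- attr(ep, "ground_truth")
    # scramble the non-face trials by replacing them with fresh noise
    nonhuman <- cat_$stimulus_id[cat_$category == "nonhuman"]
    idx <- which(ep$events$stimulus_id %in% nonhuman)
    set.seed(1000 + s)
    ep$data[idx, , ] <- rnorm(length(ep$data[idx, , ]))
    neural_rdm_series(ep, metric = "corr_distance")
  })
  scores <- aggregate_ratings(simulate_ratings(cat_, cfg, "sex"))
  behav <- behavioral_rdm(scores)
  human <- cat_$stimulus_id[cat_$category == "human"]
  win <- sers[[1]]$times > 130 & sers[[1]]$times < 250
  rho_all <- mean(rsa_timecourse(sers, behav)$rho[win])
  rho_human <- mean(rsa_timecourse(sers, behav, keep_ids = human)$rho[win])
  expect_gt(rho_human, rho_all)
})

test_that("noise ceiling is 1 for identical subjects, ~0 for independent ones", {
  cfg <- tiny_cfg()
  ser <- neural_rdm_series(tiny_epochs(cfg), metric = "corr_distance")
  same <- noise_ceiling_lower(list(ser, ser, ser))
  expect_equal(same$ceiling, rep(1, length(ser$times)))
  inds <- lapply(1:6, function(s)
    neural_rdm_series(tiny_epochs(tiny_cfg(amplitude = 0, image_amp = 0),
                                  subject_seed = s),
                      metric = "corr_distance"))
  nc <- noise_ceiling_lower(inds)
  expect_lt(max(abs(nc$ceiling)), 0.45)
  expect_true(all(abs(nc$ceiling) <= 1))
  expect_error(noise_ceiling_lower(list(ser, ser)), ">= 3")
})
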