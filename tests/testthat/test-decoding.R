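test_that("shrinkage LDA separates point clouds and matches closed-form LDA", {
  set.seed(51)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 6), 50))
  y <- rep(0:1, each = 50)
  fit <- lda_fit(x, y)
  expect_equal(predict(fit, x)$class, as.character(y))
  # identity covariance, known means: LDA weights align with mean difference
  set.seed(52)
  x2 <- rbind(matrix(rnorm(2000), ncol = 2),
              sweep(matrix(rnorm(2000), ncol = 2), 2, c(2, 1), `+`))
  fit2 <- lda_fit(x2, rep(0:1, each = 1000))
  w <- fit2$w / sqrt(sum(fit2$w^2))
  m_diff <- colMeans(x2[1001:2000, ]) - colMeans(x2[1:1000, ])
  analytic <- m_diff / sqrt(sum(m_diff^2))   # Sigma = I up to sampling noise
  expect_equal(w, analytic, tolerance = 0.05)
  expect_error(lda_fit(x, rep(0, 100)), "two classes")
})

test_that("R and C++ LDA cross-validation routes agree fold by fold", {
  set.seed(53)
  n <- 24; p <- 6; n_time <- 3
  X <- array(rnorm(p * n * n_time), c(p, n, n_time))
  labels <- rep(0:1, each = n / 2)
  folds <- lapply(1:4, function(f) {
    te <- seq(f, n, by = 4)
    list(train = setdiff(1:n, te), test = te)
  })
  acc_cpp <- eegmvpa:::cpp_cv_lda(X, labels, folds)
  acc_r <- sapply(seq_len(n_time), function(t) sapply(folds, function(fo) {
    fit <- lda_fit(t(X[, fo$train, t]), labels[fo$train])
    mean(predict(fit, t(X[, fo$test, t]))$class == as.character(labels[fo$test]))
  }))
  expect_equal(unname(acc_cpp), unname(acc_r), tolerance = 1e-12)
})

test_that("label-permuted noise decodes at chance", {
  set.seed(54)
  X <- array(rnorm(8 * 48 * 4), c(8, 48, 4))
  labels <- sample(rep(0:1, 24))
  folds <- lapply(1:8, function(f) {
    te <- seq(f, 48, by = 8)
    list(train = setdiff(1:48, te), test = te)
  })
  acc <- eegmvpa:::cpp_cv_lda(X, labels, folds)
  expect_equal(mean(acc), 0.5, tolerance = 0.12)  # binomial on 192 predictions
})

test_that("pairwise decoding finds image signal only after stimulus onset", {
  cfg <- tiny_cfg(amplitude = 0, image_amp = 6, noise_sd = 1)
  ep <- tiny_epochs(cfg)
  pw <- pairwise_image_decoding(ep)
  expect_equal(nrow(pw$pairs), choose(12, 2))
  expect_equal(dim(pw$pair_accuracy), c(choose(12, 2), length(ep$times)))
  pre <- ep$times < 0
  post <- ep$times > 100 & ep$times < 250
  expect_lt(abs(mean(pw$accuracy[pre]) - 0.5), 0.05)
  expect_gt(mean(pw$accuracy[post]), 0.85)
})

test_that("null simulations decode at chance everywhere", {
  cfg <- tiny_cfg(amplitude = 0, image_amp = 0)
  pw <- pairwise_image_decoding(tiny_epochs(cfg), store_pairs = FALSE)
  expect_equal(mean(pw$accuracy), 0.5, tolerance = 0.03)
  # single timepoints average correlated pairs, so allow wider excursions
  expect_true(all(abs(pw$accuracy - 0.5) < 0.2))
})

test_that("scheduling violations are rejected", {
  cfg <- tiny_cfg()
  ep <- tiny_epochs(cfg)
  broken <- ep
  broken$events$stimulus_id[1] <- broken$events$stimulus_id[2]
  expect_error(pairwise_image_decoding(broken), "scheduling error")
})

test_that("class decoding generalises class signal but not image identity", {
  # image-specific signal only: pairwise decoding succeeds, but held-out
  # exemplars carry no transferable class information
  cfg <- tiny_cfg(amplitude = 0, image_amp = 6, n_blocks = 6L)
  ep <- tiny_epochs(cfg)
  scores <- aggregate_ratings(simulate_ratings(stimulus_catalog(cfg), cfg,
                                               "valence"))
  split <- select_extremes(scores, 3L)
  cls <- class_decoding(ep, split, seed = 1)
  expect_equal(cls$n_folds, 3L * 6L)
  expect_lt(abs(mean(cls$accuracy) - 0.5), 0.07)
  # genuine class signal: decodable and generalising after its onset
  # (the competing attribute is silenced so its exemplar-level variance
  # does not mask the valence class direction at this tiny exemplar count)
  cfg2 <- tiny_cfg(amplitude = 10, image_amp = 0.5, n_blocks = 6L)
  cfg2$class_effect$sex$amplitude <- 0
  ep2 <- tiny_epochs(cfg2)
  cls2 <- class_decoding(ep2, split, seed = 1)
  post <- ep2$times > 110 & ep2$times < 250
  expect_gt(mean(cls2$accuracy[post]), 0.8)
  expect_lt(abs(mean(cls2$accuracy[ep2$times < 0]) - 0.5), 0.1)
})

test_that("group averaging stacks subjects and averages evenly", {
  tc <- function(a) structure(list(times = 0:3, accuracy = rep(a, 4),
                                   chance = 0.5, scheme = "class_exemplar"),
                              class = "decoding_timecourse")
  ga <- group_average(list(tc(0.4), tc(0.6)))
  expect_equal(ga$accuracy, rep(0.5, 4))
  expect_equal(dim(ga$subject_accuracy), c(2L, 4L))
  expect_identical(group_average(list(tc(0.7)))$accuracy, rep(0.7, 4))
  bad <- tc(0.5); bad$times <- 1:4
  expect_error(group_average(list(tc(0.5), bad)), "time grids")
})
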