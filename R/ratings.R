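#' Simulate a long-format rating table for one attribute
#'
#' Each rater is assigned a uniformly random subset of `ratings_per_rater`
#' stimuli (without replacement) and rates each once on the 9-point scale.
#' The rating is an affine map of the stimulus' latent attribute value to
#' the scale midpoint 5, plus Gaussian rater noise, clipped to \[1, 9\] and
#' rounded half-away-from-zero.  Subset assignment is redrawn until every
#' stimulus has at least one rating, so downstream aggregation never sees
#' unrated stimuli.
#'
#' @param catalog a [stimulus_catalog()].
#' @param cfg a [sim_config()].
#' @param attribute `"valence"` or `"sex"`.
#' @return A `data.frame` with columns `stimulus_id`, `rater_id`,
#'   `attribute`, `rating` (integer 1-9); one row per (rater, stimulus).
#' @export
simulate_ratings <- function(catalog, cfg, attribute = c("valence", "sex")) {
  attribute <- match.arg(attribute)
  n_raters <- switch(attribute, valence = cfg$n_raters_valence,
                     sex = cfg$n_raters_sex)
  k <- cfg$ratings_per_rater
  n <- nrow(catalog)
  if (k > n) stop("ratings_per_rater exceeds number of stimuli")
  if (as.numeric(n_raters) * k < n)
    stop("coverage impossible: raters x ratings_per_rater < n_stimuli")
  set.seed(stage_seed(cfg, 2L + (attribute == "sex")))
  # rejection-resample rater subsets until every stimulus is covered
  for (attempt in seq_len(10000L)) {
    subsets <- replicate(n_raters, sample.int(n, k), simplify = FALSE)
    if (length(unique(unlist(subsets))) == n) break
    if (attempt == 10000L)
      stop("could not achieve full stimulus coverage; ",
           "increase raters or ratings_per_rater")
  }
  latent <- switch(attribute, valence = catalog$latent_valence,
                   sex = catalog$latent_sex)
  idx <- unlist(subsets)
  raw <- 5 + cfg$rating_scale_sd * latent[idx] +
    rnorm(length(idx), sd = cfg$rater_noise_sd)
  rating <- as.integer(floor(pmin(pmax(raw, 1), 9) + 0.5))
  data.frame(
    stimulus_id = catalog$stimulus_id[idx],
    rater_id = rep(seq_len(n_raters) - 1L, each = k),
    attribute = attribute,
    rating = rating)
}
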