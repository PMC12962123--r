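#' Bayes-factor configuration
#'
#' Settings for JZS (Cauchy-prior) one-sample Bayes factors with interval
#' nulls: the prior scale (default 0.707, so half the prior mass lies
#' within +/-0.707 SD of the null value), the null interval in effect-size
#' units (one-sided tests use \[0, 0.5\], two-sided tests \[-0.5, 0.5\]),
#' the strong-evidence threshold (10, with its reciprocal for the null),
#' and the contiguity requirement (a decision needs `min_consecutive`
#' neighbouring samples with consistent evidence).
#'
#' @param prior_scale Cauchy prior scale on standardised effect size.
#' @param null_interval `c(lo, hi)` effect-size null interval, `lo <= hi`.
#' @param direction `"above_chance_one_sided"` (alternative: effect beyond
#'   `hi`) or `"two_sided"` (alternative: effect outside the interval on
#'   either side).
#' @param alt_threshold evidence threshold for the alternative; the null
#'   threshold is its reciprocal.
#' @param min_consecutive minimum run length of consistent samples.
#' @return A list of class `"bf_config"`.
#' @export
bf_config <- function(prior_scale = 0.707, null_interval = c(0, 0.5),
                      direction = c("above_chance_one_sided", "two_sided"),
                      alt_threshold = 10, min_consecutive = 2L) {
  direction <- match.arg(direction)
  if (null_interval[1] > null_interval[2]) stop("null interval must have lo <= hi")
  if (alt_threshold <= 1) stop("alt_threshold must exceed 1")
  structure(list(prior_scale = prior_scale, null_interval = null_interval,
                 direction = direction, alt_threshold = alt_threshold,
                 null_threshold = 1 / alt_threshold,
                 min_consecutive = as.integer(min_consecutive)),
            class = "bf_config")
}

# Marginal likelihood of an observed t statistic under a Cauchy(0, r) prior
# on effect size truncated to (lo, hi): the JZS integrand integrated by
# adaptive quadrature and normalised by the truncation mass.
jzs_marginal <- function(tstat, df, n, r, lo, hi, rel.tol = 1e-8) {
  mass <- pcauchy(hi, scale = r) - pcauchy(lo, scale = r)
  if (mass <= 0) return(NA_real_)
  # dt() warns about reduced accuracy at extreme noncentrality; the density
  # is ~0 there and the loss is far below the quadrature tolerance
  f <- function(delta) suppressWarnings(
    dt(tstat, df = df, ncp = sqrt(n) * delta) * dcauchy(delta, scale = r))
  val <- integrate(f, lo, hi, rel.tol = rel.tol, abs.tol = 1e-14,
                   stop.on.error = FALSE)$value
  val / mass
}

#' JZS interval-null Bayes factor for one sample
#'
#' Computes the Bayes factor comparing an interval alternative against an
#' interval null for a one-sample design, using a Cauchy (JZS) prior on the
#' standardised effect size centred on the null value.  The alternative
#' region is `(hi, Inf)` for one-sided tests and the two-tailed complement
#' of the null interval for two-sided tests; both marginal likelihoods use
#' the Cauchy prior truncated to their region.  A degenerate null interval
#' `[d, d]` reduces to the point-null JZS t test.
#'
#' With zero sample variance the Bayes factor is `Inf` when the mean
#' differs from the null value; when the mean equals it exactly the
#' statistic is taken as t = 0.
#'
#' @param values per-subject statistics at one timepoint (length >= 2).
#' @param null_value the chance/null level subtracted from the values
#'   (0.5 for decoding accuracy, 0 for correlations).
#' @param cfg a [bf_config()].
#' @return The Bayes factor `bf10` (> 0, possibly `Inf`).
#' @export
jzs_bf_onesample <- function(values, null_value = 0, cfg = bf_config()) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need >= 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  s <- sd(values)
  m <- mean(values) - null_value
  if (s == 0) {
    if (m != 0) return(Inf)
    tstat <- 0
  } else tstat <- m / (s / sqrt(n))
  jzs_bf_t(tstat, n, cfg)
}

#' @rdname jzs_bf_onesample
#' @param tstat observed one-sample t statistic.
#' @param n sample size (df = n - 1).
#' @export
jzs_bf_t <- function(tstat, n, cfg = bf_config()) {
  df <- n - 1
  r <- cfg$prior_scale
  lo <- cfg$null_interval[1]
  hi <- cfg$null_interval[2]
  m_null <- if (lo == hi) suppressWarnings(dt(tstat, df = df, ncp = sqrt(n) * lo))
  else jzs_marginal(tstat, df, n, r, lo, hi)
  m_alt <- if (cfg$direction == "above_chance_one_sided") {
    jzs_marginal(tstat, df, n, r, hi, Inf)
  } else {
    mass_l <- pcauchy(lo, scale = r)
    mass_u <- pcauchy(hi, scale = r, lower.tail = FALSE)
    if (lo == -Inf && hi == Inf) stop("two-sided alternative region is empty")
    (jzs_marginal(tstat, df, n, r, -Inf, lo) * mass_l +
       jzs_marginal(tstat, df, n, r, hi, Inf) * mass_u) / (mass_l + mass_u)
  }
  m_alt / m_null
}

#' Bayes-factor time series for a group-level timecourse
#'
#' Applies [jzs_bf_onesample()] at each timepoint of a per-subject stack
#' (decoding accuracies or RSA correlations) and attaches the
#' contiguity-filtered decision series from [flag_reliable()].
#'
#' @param tc a [group_average()] result (or any list with `times` and a
#'   subjects-by-timepoints matrix `subject_accuracy` or `subject_rho`).
#' @param null_value chance/null level (defaults to `tc$chance`, else 0).
#' @param cfg a [bf_config()].
#' @return A list of class `"bf_series"`: `times`, `bf10`, `decision`.
#' @export
bf_timecourse <- function(tc, null_value = NULL, cfg = bf_config()) {
  stack <- if (!is.null(tc$subject_accuracy)) tc$subject_accuracy
  else tc$subject_rho
  if (is.null(stack)) stop("tc carries no per-subject stack")
  if (is.null(null_value)) null_value <- if (!is.null(tc$chance)) tc$chance else 0
  bf10 <- apply(stack, 2, jzs_bf_onesample, null_value = null_value, cfg = cfg)
  structure(list(times = tc$times, bf10 = bf10,
                 decision = flag_reliable(bf10, cfg), cfg = cfg),
            class = "bf_series")
}

#' Bayes factors for a paired contrast of two timecourses
#'
#' Per timepoint, a one-sample JZS Bayes factor on the paired differences
#' (subject-wise `a - b`) against zero, quantifying the evidence that one
#' attribute's decoding accuracy (or correlation) exceeds the other's.
#'
#' @param tc_a,tc_b [group_average()] results over matched subjects and
#'   identical time grids.
#' @param cfg a [bf_config()]; the default one-sided configuration tests
#'   `a > b`.
#' @return A `"bf_series"` (see [bf_timecourse()]).
#' @export
bf_paired_contrast <- function(tc_a, tc_b, cfg = bf_config()) {
  sa <- if (!is.null(tc_a$subject_accuracy)) tc_a$subject_accuracy else tc_a$subject_rho
  sb <- if (!is.null(tc_b$subject_accuracy)) tc_b$subject_accuracy else tc_b$subject_rho
  if (!identical(dim(sa), dim(sb)))
    stop("subject stacks differ in shape; contrasts need matched subjects")
  if (!isTRUE(all.equal(tc_a$times, tc_b$times)))
    stop("time grids differ")
  diff_tc <- list(times = tc_a$times, subject_accuracy = sa - sb, chance = 0)
  bf_timecourse(diff_tc, null_value = 0, cfg = cfg)
}

#' Contiguity-filtered decision series
#'
#' Converts a Bayes-factor series into per-timepoint decisions: samples in
#' a run of at least `min_consecutive` consecutive `bf10 >
#' alt_threshold` values are `favor_alt`; runs of `bf10 < 1/alt_threshold`
#' are `favor_null`; everything else is `inconclusive`.  Isolated extreme
#' samples are therefore never conclusive.  Idempotent given the series.
#'
#' @param bf10 numeric vector of Bayes factors.
#' @param cfg a [bf_config()].
#' @return Factor vector with levels `favor_alt`, `favor_null`,
#'   `inconclusive`.
#' @export
flag_reliable <- function(bf10, cfg = bf_config()) {
  runs_keep <- function(flag) {
    r <- rle(flag)
    r$values <- r$values & r$lengths >= cfg$min_consecutive
    inverse.rle(r)
  }
  decision <- rep("inconclusive", length(bf10))
  decision[runs_keep(bf10 > cfg$alt_threshold)] <- "favor_alt"
  decision[runs_keep(bf10 < cfg$null_threshold)] <- "favor_null"
  factor(decision, levels = c("favor_alt", "favor_null", "inconclusive"))
}

#' Onset and peak latency with bootstrap confidence intervals
#'
#' The onset is the first post-stimulus sample whose contiguity-filtered
#' Bayes-factor decision favours the alternative; the peak is the
#' post-stimulus argmax of the group-mean timecourse.  95% confidence
#' intervals come from a percentile bootstrap over subjects: subjects are
#' resampled with replacement, and the group mean, Bayes factors, decision
#' series, onset and peak are recomputed for every resample (resamples with
#' no reliable sample contribute no onset and are dropped from the onset
#' percentile).
#'
#' @param tc a [group_average()] result with a per-subject stack.
#' @param null_value chance/null level (defaults to `tc$chance`).
#' @param cfg a [bf_config()].
#' @param n_boot bootstrap resamples (0 skips the intervals).
#' @param seed integer seed for the bootstrap.
#' @return A list of class `"latency_estimate"`: `onset_ms` (`NA` with
#'   `onset_defined = FALSE` when nothing is reliable), `peak_ms`,
#'   `peak_value`, `ci95_onset`, `ci95_peak`, `n_boot`.
#' @export
estimate_latency <- function(tc, null_value = NULL, cfg = bf_config(),
                             n_boot = 1000L, seed = 1L) {
  stack <- if (!is.null(tc$subject_accuracy)) tc$subject_accuracy
  else tc$subject_rho
  if (is.null(null_value)) null_value <- if (!is.null(tc$chance)) tc$chance else 0
  times <- tc$times
  post <- which(times >= 0)
  onset_peak <- function(mat) {
    bf10 <- apply(mat, 2, jzs_bf_onesample, null_value = null_value, cfg = cfg)
    dec <- flag_reliable(bf10, cfg)
    hit <- post[dec[post] == "favor_alt"]
    mu <- colMeans(mat)
    c(onset = if (length(hit)) times[hit[1]] else NA_real_,
      peak = times[post[which.max(mu[post])]],
      peak_value = max(mu[post]))
  }
  est <- onset_peak(stack)
  ci_onset <- ci_peak <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boots <- replicate(n_boot, onset_peak(
      stack[sample.int(nrow(stack), replace = TRUE), , drop = FALSE]))
    on <- boots["onset", ]
    if (any(!is.na(on)))
      ci_onset <- unname(quantile(on, c(0.025, 0.975), na.rm = TRUE))
    ci_peak <- unname(quantile(boots["peak", ], c(0.025, 0.975)))
  }
  structure(list(onset_ms = unname(est["onset"]),
                 onset_defined = !is.na(est["onset"]),
                 peak_ms = unname(est["peak"]),
                 peak_value = unname(est["peak_value"]),
                 ci95_onset = ci_onset, ci95_peak = ci_peak,
                 n_boot = as.integer(n_boot)),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> onset %.4g ms [%.4g, %.4g], peak %.4g ms [%.4g, %.4g] (value %.4g)\n",
              x$onset_ms, x$ci95_onset[1], x$ci95_onset[2],
              x$peak_ms, x$ci95_peak[1], x$ci95_peak[2], x$peak_value))
  invisible(x)
}
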