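#' Neural RDM at one timepoint
#'
#' Pairwise dissimilarities between stimulus-evoked patterns at a single
#' timepoint.  Two metrics are supported: `"cv_decoding"` (default) reuses
#' the cross-validated pairwise decoding accuracies from
#' [pairwise_image_decoding()] as dissimilarities, and `"corr_distance"`
#' computes 1 minus the Pearson correlation between per-condition mean
#' channel patterns.
#'
#' @param epochs an [epoch_set()].
#' @param t_index timepoint index into `epochs$times`.
#' @param metric `"cv_decoding"` or `"corr_distance"`.
#' @param pairwise for `"cv_decoding"`, a [pairwise_image_decoding()] result
#'   computed with `store_pairs = TRUE` on the same epochs.
#' @return An [rdm()] over the stimulus ids.
#' @export
neural_rdm <- function(epochs, t_index,
                       metric = c("cv_decoding", "corr_distance"),
                       pairwise = NULL) {
  metric <- match.arg(metric)
  ser <- neural_rdm_series(epochs, metric = metric, pairwise = pairwise,
                           t_index = t_index)
  rdm(ser$condensed[, 1], ser$ids, metric)
}

#' Neural RDMs for every timepoint
#'
#' Computes the condensed neural RDM at each (selected) timepoint of an
#' epoch set, the per-subject input to [rsa_timecourse()] and
#' [noise_ceiling_lower()].
#'
#' @inheritParams neural_rdm
#' @param t_index timepoint indices (default: all).
#' @return A list of class `"rdm_series"`: `ids`, `times`, `metric`, and
#'   `condensed` (pairs x timepoints matrix, rows in lexicographic pair
#'   order).
#' @export
neural_rdm_series <- function(epochs,
                              metric = c("cv_decoding", "corr_distance"),
                              pairwise = NULL, t_index = NULL) {
  metric <- match.arg(metric)
  if (is.null(t_index)) t_index <- seq_along(epochs$times)
  ids <- sort(unique(epochs$events$stimulus_id))
  if (length(ids) < 2) stop("need >= 2 conditions")
  if (metric == "cv_decoding") {
    if (is.null(pairwise) || is.null(pairwise$pair_accuracy))
      stop("metric 'cv_decoding' needs a pairwise_image_decoding() result ",
           "with store_pairs = TRUE")
    if (!identical(sort(unique(as.integer(pairwise$pairs))), as.integer(ids)))
      stop("pairwise result covers a different stimulus set")
    condensed <- pairwise$pair_accuracy[, t_index, drop = FALSE]
  } else {
    grp <- match(epochs$events$stimulus_id, ids)
    condensed <- vapply(t_index, function(ti) {
      m <- epochs$data[, , ti]          # trials x channels
      means <- rowsum(m, grp) / tabulate(grp, length(ids))
      d <- 1 - cor(t(means))
      d[lower.tri(d)]
    }, numeric(length(ids) * (length(ids) - 1) / 2))
  }
  structure(list(ids = ids, times = epochs$times[t_index],
                 condensed = condensed, metric = metric),
            class = "rdm_series")
}

#' Time-resolved neural-behavioural RSA
#'
#' Spearman rank correlation between each subject's neural RDM and a
#' behavioural RDM at every timepoint, averaged across subjects.  The
#' per-subject stack is retained for Bayes-factor inference.
#'
#' @param neural list of per-subject [neural_rdm_series()] objects over the
#'   same conditions and time grid.
#' @param behavioral an [rdm()] (e.g. [behavioral_rdm()]).
#' @param keep_ids optional condition subset (e.g. the human-face stimuli
#'   only); both RDMs are restricted before correlating.
#' @return A list of class `"rsa_timecourse"`: `times`, `rho` (group mean
#'   per timepoint), `subject_rho` (subjects x timepoints), `subset`.
#' @export
rsa_timecourse <- function(neural, behavioral, keep_ids = NULL) {
  ids <- neural[[1]]$ids
  for (ser in neural)
    if (!identical(ser$ids, ids)) stop("condition sets differ across subjects")
  if (!setequal(ids, behavioral$ids)) {
    d <- union(setdiff(ids, behavioral$ids), setdiff(behavioral$ids, ids))
    stop("neural/behavioural condition mismatch: ",
         paste(head(d, 10), collapse = ", "))
  }
  mask <- rep(TRUE, length(neural[[1]]$condensed[, 1]))
  if (!is.null(keep_ids)) {
    if (sum(ids %in% keep_ids) < 2) stop("subset must retain >= 2 conditions")
    pairs <- t(utils::combn(ids, 2))
    mask <- pairs[, 1] %in% keep_ids & pairs[, 2] %in% keep_ids
  }
  bm <- rdm_square(behavioral)                # realign to the neural id order
  ord <- match(ids, behavioral$ids)
  bm <- bm[ord, ord]
  b <- bm[lower.tri(bm)][mask]
  subject_rho <- t(vapply(neural, function(ser)
    apply(ser$condensed[mask, , drop = FALSE], 2, cor, y = b,
          method = "spearman"),
    numeric(length(neural[[1]]$times))))
  structure(list(times = neural[[1]]$times, rho = colMeans(subject_rho),
                 subject_rho = subject_rho,
                 subset = if (is.null(keep_ids)) "all" else "subset",
                 metric = neural[[1]]$metric),
            class = "rsa_timecourse")
}

#' Lower-bound noise ceiling for the RSA timecourse
#'
#' Leave-one-participant-out estimate of the best correlation any model
#' could reach given inter-subject variability: at each timepoint every
#' subject's RDM is rank-transformed and Spearman-correlated with the mean
#' rank-transformed RDM of all other subjects; the mean of these
#' correlations is the lower bound.
#'
#' @param neural list of per-subject [neural_rdm_series()] (>= 3 subjects).
#' @return A list with `times` and `ceiling` (per-timepoint lower bound in
#'   \[-1, 1\]).
#' @export
noise_ceiling_lower <- function(neural) {
  n_sub <- length(neural)
  if (n_sub < 3) stop("noise ceiling needs >= 3 subjects")
  times <- neural[[1]]$times
  n_time <- length(times)
  ceiling <- numeric(n_time)
  for (ti in seq_len(n_time)) {
    ranks <- vapply(neural, function(ser) rank(ser$condensed[, ti]),
                    numeric(nrow(neural[[1]]$condensed)))
    tot <- rowSums(ranks)
    ceiling[ti] <- mean(vapply(seq_len(n_sub), function(s)
      cor(ranks[, s], (tot - ranks[, s]) / (n_sub - 1), method = "spearman"),
      numeric(1)))
  }
  list(times = times, ceiling = ceiling)
}
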