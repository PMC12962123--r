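# Shared helpers for the time-resolved decoding drivers.

# channels x trials x timepoints view used by the C++ CV core
decoding_cube <- function(epochs) aperm(epochs$data, c(2, 1, 3))

check_block_design <- function(events) {
  tab <- table(events$stimulus_id, events$block)
  if (any(tab != 1))
    stop("scheduling error: every stimulus must appear exactly once per block")
  invisible(sort(unique(events$block)))
}

new_timecourse <- function(times, accuracy, scheme, ...) {
  structure(c(list(times = times, accuracy = accuracy, chance = 0.5,
                   scheme = scheme), list(...)),
            class = "decoding_timecourse")
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("<decoding_timecourse> %s: %d timepoints, peak %.3f @ %.4g ms\n",
              x$scheme, length(x$times), max(x$accuracy),
              x$times[which.max(x$accuracy)]))
  invisible(x)
}

#' Time-resolved pairwise image decoding
#'
#' For every unordered stimulus pair and every timepoint, a shrinkage-LDA
#' classifier is trained to discriminate the two stimuli under
#' leave-one-block-out cross-validation (trained on all blocks but one,
#' tested on the held-out block, each block serving once as test set).
#' The mean over pairs at each timepoint is a time-resolved measure of
#' image specificity in the neural signal (chance = 50%); with 900 stimuli
#' the analysis spans 404,550 unique pairs.
#'
#' @param epochs an [epoch_set()]; every stimulus must appear exactly once
#'   per block.
#' @param store_pairs keep the per-pair accuracy matrix (needed when the
#'   result feeds [neural_rdm()] with the decoding metric).
#' @return A `"decoding_timecourse"` with `accuracy` (mean over pairs per
#'   timepoint), `pairs` (2-column matrix of stimulus ids) and, if
#'   requested, `pair_accuracy` (pairs x timepoints).
#' @export
pairwise_image_decoding <- function(epochs, store_pairs = TRUE) {
  ev <- epochs$events
  blocks <- check_block_design(ev)
  stims <- sort(unique(ev$stimulus_id))
  pairs <- t(utils::combn(stims, 2))
  X <- decoding_cube(epochs)
  n_time <- length(epochs$times)
  pair_acc <- matrix(NA_real_, nrow(pairs), n_time)
  for (pi in seq_len(nrow(pairs))) {
    idx <- which(ev$stimulus_id %in% pairs[pi, ])
    labels <- as.integer(ev$stimulus_id[idx] == pairs[pi, 2])
    folds <- lapply(blocks, function(b) {
      te <- which(ev$block[idx] == b)
      list(train = setdiff(seq_along(idx), te), test = te)
    })
    acc <- cpp_cv_lda(X[, idx, , drop = FALSE], labels, folds)
    pair_acc[pi, ] <- colMeans(acc)
  }
  out <- new_timecourse(epochs$times, colMeans(pair_acc), "pairwise_image",
                        pairs = pairs, n_pairs = nrow(pairs))
  if (store_pairs) out$pair_accuracy <- pair_acc
  out
}

#' Exemplar-generalising class decoding
#'
#' Trains classifiers to discriminate two stimulus classes (e.g. low vs
#' high valence) while withholding one exemplar of each class and one block
#' from training: for each of `k` exemplar-pair iterations and each block,
#' the classifier is trained on the remaining `k - 1` exemplars per class
#' in the other blocks and tested on the two held-out exemplars in the
#' held-out block.  Above-chance accuracy therefore reflects class signals
#' that generalise to novel stimuli.  Exemplars are paired by a seeded
#' shuffle of each class.
#'
#' @param epochs an [epoch_set()].
#' @param split a [select_extremes()] class split.
#' @param seed seed for the exemplar pairing shuffle.
#' @return A `"decoding_timecourse"` (`scheme = "class_exemplar"`) whose
#'   `accuracy` is the mean over `k * n_blocks` folds per timepoint.
#' @export
class_decoding <- function(epochs, split, seed = 1L) {
  ev <- epochs$events
  blocks <- check_block_design(ev)
  idx <- which(ev$stimulus_id %in% c(split$low_ids, split$high_ids))
  if (!setequal(ev$stimulus_id[idx], c(split$low_ids, split$high_ids)))
    stop("class split references stimuli missing from the epochs")
  stim <- ev$stimulus_id[idx]
  labels <- as.integer(stim %in% split$high_ids)
  set.seed(as.integer(seed))
  low <- sample(split$low_ids)
  high <- sample(split$high_ids)
  folds <- list()
  for (i in seq_along(low)) {
    held <- c(low[i], high[i])
    for (b in blocks) {
      te <- which(stim %in% held & ev$block[idx] == b)
      tr <- which(!(stim %in% held) & ev$block[idx] != b)
      folds[[length(folds) + 1L]] <- list(train = tr, test = te)
    }
  }
  X <- decoding_cube(epochs)
  acc <- cpp_cv_lda(X[, idx, , drop = FALSE], labels, folds)
  new_timecourse(epochs$times, colMeans(acc), "class_exemplar",
                 attribute = split$attribute, k = split$k,
                 n_folds = length(folds))
}

#' Group-average decoding (or RSA) timecourses
#'
#' Unweighted mean across subjects, retaining the per-subject stack for
#' group-level Bayes-factor inference.
#'
#' @param per_subject list of `"decoding_timecourse"` objects (or any lists
#'   with identical `times` and an `accuracy` vector).
#' @return A `"decoding_timecourse"` with `accuracy` (group mean) and
#'   `subject_accuracy` (subjects x timepoints matrix).
#' @export
group_average <- function(per_subject) {
  times <- per_subject[[1]]$times
  for (tc in per_subject)
    if (!isTRUE(all.equal(tc$times, times)))
      stop("time grids differ across subjects")
  stack <- do.call(rbind, lapply(per_subject, `[[`, "accuracy"))
  new_timecourse(times, colMeans(stack), per_subject[[1]]$scheme,
                 subject_accuracy = stack, n_subjects = nrow(stack))
}
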