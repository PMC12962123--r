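#' Aggregate a rating table to per-stimulus mean scores
#'
#' Collates all raters and computes the arithmetic mean rating for each
#' stimulus, recording how many raters contributed.
#'
#' @param table long-format rating `data.frame` with columns `stimulus_id`,
#'   `rater_id`, `attribute`, `rating` (see [simulate_ratings()]).
#' @return A `data.frame` (`stimulus_id`, `mean_rating`, `n_raters`,
#'   `attribute`), one row per stimulus, sorted by `stimulus_id`.
#' @export
aggregate_ratings <- function(table) {
  stopifnot(all(c("stimulus_id", "rating") %in% names(table)))
  sp <- split(table$rating, table$stimulus_id)
  out <- data.frame(
    stimulus_id = as.integer(names(sp)),
    mean_rating = vapply(sp, mean, numeric(1)),
    n_raters = lengths(sp),
    attribute = table$attribute[1],
    row.names = NULL)
  out[order(out$stimulus_id), , drop = FALSE]
}

# Fail loudly if any catalogue stimulus is missing from the scores.
check_coverage <- function(scores, ids) {
  missing <- setdiff(ids, scores$stimulus_id)
  if (length(missing))
    stop("unrated stimuli: ", paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  invisible(TRUE)
}

#' Select the extreme-scoring stimuli for class decoding
#'
#' Returns the `k` lowest- and `k` highest-scoring stimuli, the two classes
#' used for exemplar-generalising decoding (e.g. 200 most negative vs 200
#' most positive faces).  Ties are broken by ascending `stimulus_id`.
#'
#' @param scores output of [aggregate_ratings()].
#' @param k class size (default 200).
#' @return A list of class `"class_split"` with integer vectors `low_ids`
#'   and `high_ids` (each length `k`) and the attribute tag.
#' @export
select_extremes <- function(scores, k = 200L) {
  n <- nrow(scores)
  if (2 * k > n)
    stop("2k = ", 2 * k, " exceeds the ", n, " available stimuli")
  ord <- order(scores$mean_rating, scores$stimulus_id)
  structure(list(low_ids = scores$stimulus_id[ord[seq_len(k)]],
                 high_ids = scores$stimulus_id[ord[seq.int(n - k + 1, n)]],
                 attribute = scores$attribute[1], k = as.integer(k)),
            class = "class_split")
}

#' Behavioural RDM from mean ratings
#'
#' Dissimilarity between two stimuli is the absolute difference of their
#' group-mean ratings; for 900 stimuli this yields 404,550 unique pairwise
#' values.
#'
#' @param scores output of [aggregate_ratings()] (>= 2 stimuli).
#' @return An [rdm()] with metric `"abs_rating_diff"`.
#' @export
behavioral_rdm <- function(scores) {
  if (nrow(scores) < 2) stop("need >= 2 stimuli")
  scores <- scores[order(scores$stimulus_id), , drop = FALSE]
  d <- dist(scores$mean_rating, method = "manhattan")
  rdm(as.numeric(d), scores$stimulus_id, metric = "abs_rating_diff")
}

#' Split-half reliability of the behavioural RDM
#'
#' Raters are repeatedly split at random into two equal groups; each
#' group's ratings are aggregated and turned into a behavioural RDM, and
#' the Spearman correlation between the two condensed RDMs is recorded.
#' Stimuli unrated in either half of an iteration are excluded pairwise for
#' that iteration.  With an odd rater count one rater is dropped at random
#' per iteration.
#'
#' @param table long-format rating table (>= 4 raters).
#' @param n_iter number of random splits (default 100).
#' @param seed integer seed.
#' @return A list with `rho` (length `n_iter`), `mean`, `median`, `range`.
#' @export
split_half_reliability <- function(table, n_iter = 100L, seed = 1L) {
  raters <- unique(table$rater_id)
  if (length(raters) < 4) stop("need >= 4 raters")
  set.seed(as.integer(seed))
  rho <- vapply(seq_len(n_iter), function(i) {
    rs <- sample(raters)
    if (length(rs) %% 2 == 1) rs <- rs[-1]
    half <- length(rs) / 2
    s1 <- aggregate_ratings(table[table$rater_id %in% rs[seq_len(half)], ])
    s2 <- aggregate_ratings(table[table$rater_id %in% rs[-seq_len(half)], ])
    common <- intersect(s1$stimulus_id, s2$stimulus_id)
    r1 <- behavioral_rdm(s1[s1$stimulus_id %in% common, ])
    r2 <- behavioral_rdm(s2[s2$stimulus_id %in% common, ])
    cor(r1$condensed, r2$condensed, method = "spearman")
  }, numeric(1))
  list(rho = rho, mean = mean(rho), median = median(rho), range = range(rho))
}

#' Spearman correlation between two attributes' mean ratings
#'
#' Two-tailed Spearman rank correlation across stimuli between, e.g., mean
#' valence and mean masculinity scores.  Ties get average ranks; the
#' p-value uses the t approximation.
#'
#' @param valence,sex outputs of [aggregate_ratings()] over the same
#'   stimulus set.
#' @return A list with `rho`, `p`, `n`.
#' @export
correlate_attributes <- function(valence, sex) {
  valence <- valence[order(valence$stimulus_id), ]
  sex <- sex[order(sex$stimulus_id), ]
  if (!identical(valence$stimulus_id, sex$stimulus_id))
    stop("stimulus sets differ between the two attributes")
  rho <- cor(valence$mean_rating, sex$mean_rating, method = "spearman")
  n <- nrow(valence)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}
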