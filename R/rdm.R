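#' Representational dissimilarity matrix (condensed form)
#'
#' Stores the lower triangle of a symmetric condition-by-condition
#' dissimilarity matrix as a condensed vector of length `n(n-1)/2`, in
#' lexicographic pair order (1,2), (1,3), ..., (2,3), ... — the same order
#' [stats::dist()] uses.
#'
#' @param condensed numeric vector of pairwise dissimilarities.
#' @param ids condition identifiers (length `n`).
#' @param metric character tag recording how the dissimilarities were
#'   computed.
#' @return A list of class `"rdm"`.
#' @export
rdm <- function(condensed, ids, metric = "unknown") {
  n <- length(ids)
  if (length(condensed) != n * (n - 1) / 2)
    stop("condensed length ", length(condensed), " does not match ",
         n, " conditions (expected ", n * (n - 1) / 2, ")")
  structure(list(ids = ids, condensed = as.numeric(condensed),
                 metric = metric), class = "rdm")
}

#' Expand a condensed RDM to its square matrix
#'
#' @param x an [rdm()].
#' @return Symmetric matrix with zero diagonal, dimnames = condition ids.
#' @export
rdm_square <- function(x) {
  n <- length(x$ids)
  m <- matrix(0, n, n, dimnames = list(x$ids, x$ids))
  m[lower.tri(m)] <- x$condensed
  m + t(m)
}

#' Condense a square dissimilarity matrix to an RDM
#'
#' @param m symmetric matrix with zero diagonal.
#' @param ids condition ids (default from dimnames).
#' @param metric metric tag.
#' @return An [rdm()].
#' @export
rdm_condense <- function(m, ids = rownames(m), metric = "unknown") {
  if (is.null(ids)) ids <- seq_len(nrow(m))
  rdm(m[lower.tri(m)], ids, metric)
}

#' Restrict an RDM to a subset of conditions
#'
#' @param x an [rdm()].
#' @param keep_ids condition ids to retain (order follows `x$ids`).
#' @return An [rdm()] over the kept conditions.
#' @export
rdm_subset <- function(x, keep_ids) {
  keep <- x$ids %in% keep_ids
  if (sum(keep) < 2) stop("subset must retain >= 2 conditions")
  if (all(keep)) return(x)
  m <- rdm_square(x)[keep, keep]
  rdm_condense(m, ids = x$ids[keep], metric = x$metric)
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %d conditions, %d pairs, metric = %s\n",
              length(x$ids), length(x$condensed), x$metric))
  invisible(x)
}
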