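#' Ledoit-Wolf shrinkage covariance
#'
#' Analytic shrinkage of the sample covariance toward a scaled identity
#' target, the standard remedy when the channel count approaches the trial
#' count and the pooled covariance would be singular.  The shrinkage
#' intensity minimises the expected Frobenius loss.
#'
#' @param xc matrix of centred observations (rows = observations).
#' @return A list with the shrunk covariance `sigma`, the intensity
#'   `lambda`, and the target scale `mu`.
#' @export
shrinkage_cov <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  s2 <- sum(s^2)
  d2 <- (s2 - p * mu^2) / p
  xsx <- rowSums((xc %*% s) * xc)
  norms4 <- rowSums(xc^2)^2
  b2 <- min(sum(norms4 - 2 * xsx + s2) / n^2 / p, d2)
  lambda <- if (d2 > 0) b2 / d2 else 1
  sigma <- (1 - lambda) * s
  diag(sigma) <- diag(sigma) + lambda * mu
  list(sigma = sigma, lambda = lambda, mu = mu)
}

#' Fit a two-class shrinkage LDA discriminant
#'
#' Linear discriminant analysis with equal priors and a pooled within-class
#' covariance regularised by [shrinkage_cov()].  The discriminant returns
#' class posterior probabilities; the class with the higher posterior is
#' the prediction.
#'
#' @param x trials-by-channels matrix of training patterns.
#' @param labels binary vector (two levels; coerced to 0/1 by first level).
#' @return A list of class `"lda_model"` with weights `w`, offset `c`, and
#'   the class `levels`.
#' @export
lda_fit <- function(x, labels) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("exactly two classes required")
  if (min(table(f)) < 2) stop("need >= 2 trials per class")
  x <- as.matrix(x)
  m0 <- colMeans(x[f == levels(f)[1], , drop = FALSE])
  m1 <- colMeans(x[f == levels(f)[2], , drop = FALSE])
  xc <- x - rbind(m0, m1)[as.integer(f), ]
  sigma <- shrinkage_cov(xc)$sigma
  w <- tryCatch(solve(sigma, m1 - m0),
                error = function(e) MASS_ginv(sigma) %*% (m1 - m0))
  w <- as.numeric(w)
  structure(list(w = w, c = sum(w * (m0 + m1)) / 2, levels = levels(f)),
            class = "lda_model")
}

# Moore-Penrose fallback for a (numerically) singular pooled covariance.
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(m)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Predict classes and posteriors from a fitted discriminant
#'
#' @param object an [lda_fit()] model.
#' @param newdata trials-by-channels matrix.
#' @param ... unused.
#' @return A `data.frame` with `class` (predicted label) and `posterior`
#'   (probability of the second level).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  score <- as.matrix(newdata) %*% object$w - object$c
  data.frame(class = object$levels[1 + (score > 0)],
             posterior = stats::plogis(score)[, 1])
}
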