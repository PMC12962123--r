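#' Luminance and contrast of a grayscale image
#'
#' Luminance is the mean pixel intensity and contrast the population
#' standard deviation of pixel intensities (0-255 scale).
#'
#' @param image 2-D numeric matrix of pixel intensities.
#' @return A list with `luminance` and `contrast`.
#' @export
basic_stats <- function(image) {
  if (length(image) == 0) stop("empty image")
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  mu <- mean(image)
  list(luminance = mu, contrast = sqrt(mean((image - mu)^2)))
}

#' Low- and high-band radial spatial-frequency content
#'
#' Computes the 2-D DFT amplitude spectrum, bins components by integer
#' radial frequency (DC excluded), averages amplitude within each radius to
#' form the radial profile, median-splits the set of radii into a low and a
#' high band, and returns the mean profile value in each band.  Because
#' only the amplitude spectrum is used, the result is invariant to image
#' translation.
#'
#' @param image square 2-D numeric matrix, side >= 8.
#' @param power if `TRUE` average the power spectrum instead of amplitude.
#' @return A list with `low_sf`, `high_sf`, and the full radial `profile`.
#' @export
radial_sf_bands <- function(image, power = FALSE) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop("image must be square")
  n <- nrow(image)
  if (n < 8) stop("image side must be >= 8")
  amp <- Mod(stats::fft(image)) / length(image)
  if (power) amp <- amp^2
  k <- c(0:(n %/% 2), rev(seq_len(n - n %/% 2 - 1)))  # wrapped frequencies
  radius <- round(sqrt(outer(k^2, k^2, `+`)))
  keep <- radius > 0  # DC excluded; it is the luminance, measured separately
  profile <- tapply(amp[keep], radius[keep], mean)
  radii <- as.numeric(names(profile))
  med <- median(radii)
  list(low_sf = mean(profile[radii <= med]),
       high_sf = mean(profile[radii > med]),
       profile = profile)
}

#' Image-statistics table for a set of stimuli
#'
#' @param paths named or unnamed character vector of PNG paths.
#' @param stimulus_id optional ids (default 0-based along `paths`).
#' @return A `data.frame` with `stimulus_id`, `luminance`, `contrast`,
#'   `low_sf`, `high_sf`.
#' @export
image_stats <- function(paths, stimulus_id = seq_along(paths) - 1L) {
  rows <- lapply(paths, function(p) {
    img <- read_image(p)
    c(unlist(basic_stats(img)),
      unlist(radial_sf_bands(img)[c("low_sf", "high_sf")]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(stimulus_id = stimulus_id, out, row.names = NULL)
}

#' Pooled-variance two-sample t test between stimulus groups
#'
#' Independent-samples Student t test (pooled variance, df = n1 + n2 - 2,
#' two-tailed) comparing one image measure between two groups, e.g. the 200
#' lowest- vs 200 highest-rated stimuli (df = 398).
#'
#' @param x,y numeric vectors (each length >= 2), e.g. columns of
#'   [image_stats()] split by a [select_extremes()] class split.
#' @return A list with `t`, `df`, `p`, and `degenerate` (`TRUE` when the
#'   pooled variance is zero).
#' @export
compare_groups <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 values")
  df <- length(x) + length(y) - 2
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = df, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0,
                degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}
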