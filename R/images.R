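#' Simulate grayscale stimulus images
#'
#' Writes one square 8-bit grayscale PNG per stimulus.  Each image is
#' Gaussian pixel noise around a class-dependent mean intensity; non-face
#' images can additionally receive a mean-intensity offset
#' (`image_class_offset`) and a low-spatial-frequency sinusoidal grating
#' (`image_lowfreq_amplitude`, `image_lowfreq_cycles` cycles per image with
#' a per-stimulus random phase and orientation).  These knobs make
#' luminance, contrast and band-limited spectral content controllable per
#' class, which is what the low-level image-statistics controls measure.
#'
#' @param catalog a [stimulus_catalog()].
#' @param cfg a [sim_config()]; `image_size` must be >= 32.
#' @param dir output directory (created if missing).
#' @return Invisibly, a `data.frame` with `stimulus_id`, `category`, `path`.
#' @export
simulate_images <- function(catalog, cfg, dir) {
  sz <- cfg$image_size
  if (sz < 32) stop("image size must be >= 32 pixels")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(stage_seed(cfg, 5L))
  xy <- seq_len(sz) / sz
  paths <- character(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    nonface <- catalog$category[i] == "nonhuman"
    mu <- cfg$image_mean + if (nonface) cfg$image_class_offset else 0
    img <- matrix(rnorm(sz * sz, mean = mu, sd = cfg$image_sd), sz, sz)
    if (nonface && cfg$image_lowfreq_amplitude > 0) {
      theta <- runif(1, 0, pi)
      phase <- runif(1, 0, 2 * pi)
      grid <- outer(xy * sin(theta), xy * cos(theta), `+`)
      img <- img + cfg$image_lowfreq_amplitude *
        sin(2 * pi * cfg$image_lowfreq_cycles * grid + phase)
    }
    img <- pmin(pmax(img, 0), 255)
    paths[i] <- file.path(dir, sprintf("stim_%04d.png", catalog$stimulus_id[i]))
    png::writePNG(img / 255, paths[i])
  }
  invisible(data.frame(stimulus_id = catalog$stimulus_id,
                       category = catalog$category, path = paths))
}

#' Read a grayscale image as a 0-255 intensity matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix of pixel intensities on the 0-255 scale.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]  # collapse grayscale channels
  img * 255
}
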