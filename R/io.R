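#' Write an epoch set to its on-disk container
#'
#' The container is a directory with `epochs.bin` (32-bit little-endian
#' floats, C order: timepoint fastest, then channel, then trial),
#' `meta.json` (dims, channel names, sample rate, 1-based index of the
#' t = 0 sample) and `events.csv` (trial, sequence, block, stimulus_id).
#'
#' @param epochs an [epoch_set()].
#' @param path container directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(epochs$data)
  con <- file(file.path(path, "epochs.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4, endian = "little")
  zero_idx <- which.min(abs(epochs$times))
  meta <- list(dims = d, channel_names = epochs$channels,
               sample_rate_hz = epochs$sample_rate,
               time_zero_index = zero_idx,
               bad_channels = epochs$bad_channels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(epochs$events, file.path(path, "events.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an epoch set from its on-disk container
#'
#' Validates the binary size and the event count against `meta.json` before
#' reconstructing the array, so truncated or mismatched containers fail
#' with an explicit format error.
#'
#' @param path container directory written by [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  bin <- file.path(path, "epochs.bin")
  expected <- prod(as.numeric(d)) * 4
  actual <- file.info(bin)$size
  if (is.na(actual) || actual != expected)
    stop("format error: epochs.bin has ", actual, " bytes, expected ",
         expected, " for dims ", paste(d, collapse = " x "))
  con <- file(bin, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = prod(d), size = 4,
               endian = "little")
  data <- aperm(array(x, dim = rev(d)), c(3, 2, 1))
  events <- read.csv(file.path(path, "events.csv"))
  if (nrow(events) != d[1])
    stop("format error: events.csv has ", nrow(events),
         " rows, expected ", d[1], " trials")
  dt <- 1000 / meta$sample_rate_hz
  times <- (seq_len(d[3]) - meta$time_zero_index) * dt
  epoch_set(data, times, meta$sample_rate_hz, events,
            channels = meta$channel_names,
            bad_channels = as.character(unlist(meta$bad_channels)))
}
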