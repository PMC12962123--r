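#' Build the rapid serial presentation schedule
#'
#' Lays out the full trial sequence for one recording session: stimuli are
#' shown in sequences of `trials_per_sequence` trials, and every
#' `sequences_per_block` consecutive sequences form a block containing each
#' stimulus exactly once in random order.  With the defaults this yields
#' 72 sequences of 150 trials, i.e. 10,800 trials over 12 blocks (12
#' presentations of each of 900 stimuli).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed overriding the config-derived one, so
#'   each subject can receive a different randomised order.
#' @return A `data.frame` with columns `trial` (1-based, session-wide),
#'   `sequence`, `block`, `stimulus_id`.
#' @export
build_schedule <- function(cfg, seed = NULL) {
  per_block <- cfg$trials_per_sequence * cfg$sequences_per_block
  if (per_block != cfg$n_stimuli)
    stop("trials_per_sequence * sequences_per_block (", per_block,
         ") must equal n_stimuli (", cfg$n_stimuli, ")")
  set.seed(if (is.null(seed)) stage_seed(cfg, 4L) else as.integer(seed))
  stim <- unlist(lapply(seq_len(cfg$n_blocks),
                        function(b) sample.int(cfg$n_stimuli) - 1L))
  n_trials <- cfg$n_blocks * cfg$n_stimuli
  data.frame(
    trial = seq_len(n_trials),
    sequence = rep(seq_len(cfg$n_blocks * cfg$sequences_per_block),
                   each = cfg$trials_per_sequence),
    block = rep(seq_len(cfg$n_blocks), each = cfg$n_stimuli),
    stimulus_id = stim)
}
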