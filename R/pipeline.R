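#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations and global options of [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param preproc a [preproc_config()] (used when `use_raw_preproc`).
#' @param bf a [bf_config()].
#' @param k_extremes class size for [select_extremes()] (200 at full scale).
#' @param rsa_metric neural RDM metric (see [neural_rdm_series()]).
#' @param use_raw_preproc simulate continuous recordings and run the full
#'   preprocessing chain instead of generating epochs directly.
#' @param n_boot bootstrap resamples for latency intervals.
#' @param stages character subset of
#'   `c("behavior", "images", "decode", "rsa", "infer")`; the simulation
#'   stage always runs.  Stages depending on a skipped stage are skipped.
#' @param seed global integer seed (overrides `sim$seed`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), preproc = preproc_config(),
                            bf = bf_config(), k_extremes = 200L,
                            rsa_metric = "cv_decoding",
                            use_raw_preproc = FALSE, n_boot = 200L,
                            stages = c("behavior", "images", "decode",
                                       "rsa", "infer"),
                            seed = sim$seed) {
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, preproc = preproc, bf = bf,
                 k_extremes = as.integer(k_extremes),
                 rsa_metric = rsa_metric,
                 use_raw_preproc = use_raw_preproc,
                 n_boot = as.integer(n_boot), stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tc <- function(tc, path) {
  df <- data.frame(time_ms = tc$times, mean = tc$accuracy %||% tc$rho)
  stack <- tc$subject_accuracy %||% tc$subject_rho
  if (!is.null(stack)) {
    colnames_stack <- sprintf("subject_%02d", seq_len(nrow(stack)))
    df <- cbind(df, setNames(as.data.frame(t(stack)), colnames_stack))
  }
  write.csv(df, path, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage: simulate ratings/images/epochs, aggregate
#' behaviour and build behavioural RDMs, image-statistics controls,
#' pairwise and class decoding per subject, RSA (all stimuli and the
#' human-face subset) with noise ceiling, and Bayes-factor inference with
#' latency estimates.  All outputs are CSV/JSON under `out_dir`, and a
#' manifest records the configuration and output checksums so a run is
#' reproducible from its seed.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- cfg$sim
  res <- list()
  catalog <- stimulus_catalog(sim)
  write.csv(catalog, file.path(out_dir, "catalog.csv"), row.names = FALSE)

  scores <- splits <- list()
  if ("behavior" %in% cfg$stages) {
    for (a in c("valence", "sex")) {
      tab <- simulate_ratings(catalog, sim, a)
      write.csv(tab, file.path(out_dir, sprintf("ratings_%s.csv", a)),
                row.names = FALSE)
      scores[[a]] <- aggregate_ratings(tab)
      check_coverage(scores[[a]], catalog$stimulus_id)
      splits[[a]] <- select_extremes(scores[[a]], cfg$k_extremes)
      write.csv(scores[[a]], file.path(out_dir, sprintf("scores_%s.csv", a)),
                row.names = FALSE)
    }
    res$attribute_correlation <-
      correlate_attributes(scores$valence, scores$sex)
    res$scores <- scores
  }

  if ("images" %in% cfg$stages && "behavior" %in% cfg$stages) {
    img_dir <- file.path(out_dir, "stimuli")
    manifest_img <- simulate_images(catalog, sim, img_dir)
    stats <- image_stats(manifest_img$path, manifest_img$stimulus_id)
    write.csv(stats, file.path(out_dir, "image_stats.csv"), row.names = FALSE)
    comps <- list()
    for (a in names(splits))
      for (m in c("luminance", "contrast", "low_sf", "high_sf"))
        comps[[paste(a, m, sep = "_")]] <- compare_groups(
          stats[[m]][stats$stimulus_id %in% splits[[a]]$low_ids],
          stats[[m]][stats$stimulus_id %in% splits[[a]]$high_ids])
    res$image_comparisons <- comps
    jsonlite::write_json(comps, file.path(out_dir, "image_comparisons.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("decode" %in% cfg$stages && "behavior" %in% cfg$stages) {
    class_tc <- list(valence = list(), sex = list())
    pw_list <- list()
    rdm_series <- list()
    for (s in seq_len(sim$n_subjects)) {
      schedule <- build_schedule(sim, seed = stage_seed(sim, 100L + s))
      epochs <- if (cfg$use_raw_preproc) {
        raw <- simulate_raw(catalog, schedule, sim,
                            subject_seed = stage_seed(sim, 200L + s))
        preprocess_raw(raw, cfg$preproc)
      } else {
        simulate_epochs(catalog, schedule, sim,
                        subject_seed = stage_seed(sim, 200L + s))
      }
      pw <- pairwise_image_decoding(epochs)
      pw_list[[s]] <- pw
      for (a in c("valence", "sex"))
        class_tc[[a]][[s]] <- class_decoding(epochs, splits[[a]],
                                             seed = stage_seed(sim, 300L + s))
      if ("rsa" %in% cfg$stages)
        rdm_series[[s]] <- neural_rdm_series(
          epochs, metric = cfg$rsa_metric,
          pairwise = if (cfg$rsa_metric == "cv_decoding") pw)
    }
    res$pairwise <- group_average(pw_list)
    write_tc(res$pairwise, file.path(out_dir, "decoding_pairwise.csv"))
    res$class <- lapply(class_tc, group_average)
    for (a in names(res$class))
      write_tc(res$class[[a]],
               file.path(out_dir, sprintf("decoding_class_%s.csv", a)))

    if ("rsa" %in% cfg$stages) {
      res$rsa <- list()
      human_ids <- catalog$stimulus_id[catalog$category == "human"]
      for (a in c("valence", "sex")) {
        brdm <- behavioral_rdm(scores[[a]])
        res$rsa[[a]] <- rsa_timecourse(rdm_series, brdm)
        res$rsa[[paste0(a, "_human")]] <-
          rsa_timecourse(rdm_series, brdm, keep_ids = human_ids)
        write_tc(res$rsa[[a]], file.path(out_dir, sprintf("rsa_%s.csv", a)))
        write_tc(res$rsa[[paste0(a, "_human")]],
                 file.path(out_dir, sprintf("rsa_%s_human.csv", a)))
      }
      if (length(rdm_series) >= 3) {
        nc <- noise_ceiling_lower(rdm_series)
        write.csv(data.frame(time_ms = nc$times, ceiling = nc$ceiling),
                  file.path(out_dir, "noise_ceiling.csv"), row.names = FALSE)
        res$noise_ceiling <- nc
      }
    }

    if ("infer" %in% cfg$stages) {
      res$bf <- res$latency <- list()
      for (a in c("valence", "sex")) {
        bf <- bf_timecourse(res$class[[a]], cfg = cfg$bf)
        res$bf[[a]] <- bf
        write.csv(data.frame(time_ms = bf$times, bf10 = bf$bf10,
                             decision = bf$decision),
                  file.path(out_dir, sprintf("bf_class_%s.csv", a)),
                  row.names = FALSE)
        res$latency[[a]] <- estimate_latency(
          res$class[[a]], cfg = cfg$bf, n_boot = cfg$n_boot,
          seed = stage_seed(sim, 400L))
      }
      res$bf$contrast <- bf_paired_contrast(res$class$valence,
                                            res$class$sex, cfg = cfg$bf)
      jsonlite::write_json(
        lapply(res$latency, unclass), file.path(out_dir, "latency.json"),
        auto_unbox = TRUE, digits = NA)
    }
  }

  outputs <- list.files(out_dir, recursive = TRUE)
  outputs <- outputs[outputs != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("eegmvpa")),
    seed = cfg$seed, stages = cfg$stages,
    k_extremes = cfg$k_extremes, rsa_metric = cfg$rsa_metric,
    n_subjects = sim$n_subjects, n_stimuli = sim$n_stimuli,
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
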