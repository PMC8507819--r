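# End-to-end orchestration: simulate (or read) -> score -> summarise ->
# compare, writing the run's tables and resolved configuration to disk.

#' Run configuration
#'
#' @param input_dir directory of recording CSVs (with sidecar JSON
#'   metadata), or `NULL` to simulate from `simulate_config`.
#' @param simulate_config a [cohort_config()] (used when `input_dir` is
#'   `NULL`).
#' @param rula a [rula_config()].
#' @param alpha significance level for all comparisons (default 0.05).
#' @param target_rate resample input recordings to this rate when their
#'   rate is an integer multiple of it (`NULL` keeps the native rate).
#' @param output_dir where run artifacts are written.
#' @param seed integer seed for the simulation branch.
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir = NULL, simulate_config = cohort_config(),
                       rula = rula_config(), alpha = 0.05, target_rate = 24,
                       output_dir = "results", seed = 1) {
  if (alpha <= 0 || alpha >= 1) abort_config("alpha must be in (0, 1)")
  structure(list(input_dir = input_dir, simulate_config = simulate_config,
                 rula = rula, alpha = alpha, target_rate = target_rate,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

.read_input_dir <- function(dir, target_rate, rula_cfg) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) abort_input(paste0("no recording CSVs in ", dir))
  lapply(files, function(f) {
    rec <- read_recording(f)
    if (!is.null(target_rate) && rec$sampling_rate != target_rate) {
      rec <- resample_recording(rec, target_rate)
    }
    rec
  })
}

#' Score, summarise and compare a cohort of recordings
#'
#' The full analysis chain on either simulated or on-disk recordings:
#' per-frame RULA scores are reduced to per-subject risk summaries, the
#' group table (median/IQD, rel. av. RST, ERP per outcome, occupation and
#' concept), the score-time distribution table, and the two comparison
#' tables (concepts within occupation; occupations within concept). With
#' fewer than two pairs the comparisons are skipped with a warning rather
#' than aborting. Deterministic given (inputs, config, seed).
#'
#' @param cfg a [run_config()].
#' @return list with `subject_summaries`, `cohort_table`, `distributions`,
#'   `dwc_comparisons`, `occupation_comparisons`, `ground_truth` (simulated
#'   runs) and `config`; tables are also written under `cfg$output_dir`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  rula_cfg <- cfg$rula
  dist_rows <- list()
  collect_dist <- function(scores, meta) {
    maxima <- rula_outcome_maxima()
    rows <- lapply(rula_outcomes(), function(oc) {
      d <- time_distribution(outcome_series(scores, oc), maxima[[oc]])
      data.frame(subject_id = meta$subject_id, occupation = meta$occupation,
                 dwc = meta$dwc, outcome = oc,
                 score = as.integer(names(d$rel_time)),
                 rel_time = unname(d$rel_time), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  gt <- NULL
  if (is.null(cfg$input_dir)) {
    sim_cfg <- cfg$simulate_config
    sim_cfg$seed <- cfg$seed
    res <- generate_cohort(sim_cfg, rula_cfg, handler = function(rec, g) {
      sc <- score_recording(rec, rula_cfg)
      meta <- attr(sc, "meta")
      dist_rows[[length(dist_rows) + 1L]] <<- collect_dist(sc, meta)
      summarize_subject(sc)
    })
    summaries <- do.call(rbind, res$recordings)
    gt <- res$ground_truth
  } else {
    recs <- .read_input_dir(cfg$input_dir, cfg$target_rate, rula_cfg)
    summaries <- do.call(rbind, lapply(recs, function(rec) {
      sc <- score_recording(rec, rula_cfg)
      dist_rows[[length(dist_rows) + 1L]] <<- collect_dist(sc, attr(sc, "meta"))
      summarize_subject(sc)
    }))
  }

  cohort_table <- summarize_cohort(summaries)
  distributions <- do.call(rbind, dist_rows)

  n_subj <- length(unique(summaries$subject_id[summaries$occupation ==
                                                 summaries$occupation[1]]))
  comparisons_possible <- n_subj >= 2 &&
    length(unique(summaries$dwc)) == 4
  dwc_comp <- occ_comp <- NULL
  if (comparisons_possible) {
    occs <- unique(summaries$occupation)
    dwc_comp <- do.call(rbind, lapply(intersect(c("D", "DA"), occs),
      function(o) compare_dwcs(summaries, o, alpha = cfg$alpha)))
    if (length(occs) == 2) {
      occ_comp <- compare_occupations(summaries, alpha = cfg$alpha)
    }
  } else {
    warning("fewer than 2 subjects or incomplete DWC coverage: comparisons skipped",
            call. = FALSE)
  }

  out <- list(subject_summaries = summaries, cohort_table = cohort_table,
              distributions = distributions, dwc_comparisons = dwc_comp,
              occupation_comparisons = occ_comp, ground_truth = gt,
              config = cfg)
  if (!is.null(cfg$output_dir)) write_run_artifacts(out, cfg$output_dir)
  out
}

#' Write the run's tables and resolved configuration
#'
#' Delimited text (CSV) per table plus a JSON dump of the resolved
#' configuration and seed, so a run can be reproduced exactly.
#'
#' @param run output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(run$subject_summaries, "subject_summaries")
  wr(format_cohort_table(run$cohort_table), "cohort_risk_table")
  wr(run$distributions, "score_time_distributions")
  wr(run$dwc_comparisons, "dwc_comparisons")
  wr(run$occupation_comparisons, "occupation_comparisons")
  wr(run$ground_truth, "ground_truth")
  cfg <- run$config
  rula_list <- unclass(cfg$rula)
  rula_list$static_window <- unclass(rula_list$static_window)
  jsonlite::write_json(
    list(alpha = cfg$alpha, seed = cfg$seed, target_rate = cfg$target_rate,
         rula = rula_list, input_dir = cfg$input_dir,
         n_pairs = cfg$simulate_config$n_pairs,
         duration_s = cfg$simulate_config$duration_s,
         sampling_rate = cfg$simulate_config$sampling_rate),
    file.path(dir, "resolved_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Format the group risk table for reporting
#'
#' Rounds rel. av. RST and ERP to two decimals (half-up) and medians/IQDs
#' to the half-integers the rank statistics produce.
#'
#' @param cohort_table from [summarize_cohort()].
#' @return data.frame with rounded reporting columns.
#' @export
format_cohort_table <- function(cohort_table) {
  out <- cohort_table
  out$rel_av_rst <- round_half_up(out$rel_av_rst, 2)
  out$erp_pct <- round_half_up(out$erp_pct, 2)
  out$median <- round_half_up(out$median, 1)
  out$iqd <- round_half_up(out$iqd, 2)
  out
}
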