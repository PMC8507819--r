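# Time-in-score exposure statistics: relative time per score value, the
# time-weighted mean score (relative average risk score over time,
# "rel. av. RST") and its percentage of the outcome's maximum (ergonomic
# risk potential, ERP).

#' Relative time spent in each score value
#'
#' @param scores integer score sequence (one value per frame).
#' @param max_score maximum possible score for this outcome (7 for the
#'   grand score; 6 for trunk, neck, upper arm, wrist; 3 for lower arm).
#' @return a `score_time_distribution`: list with `rel_time` (named numeric,
#'   fractions summing to 1 over the observed score values) and `max_score`.
#' @export
time_distribution <- function(scores, max_score) {
  if (length(scores) == 0) abort_input("empty score sequence")
  if (any(!is.finite(scores) | scores != round(scores))) {
    abort_integrity("scores must be whole numbers")
  }
  if (any(scores < 1 | scores > max_score)) {
    abort_integrity(sprintf("score outside 1..%d observed", max_score))
  }
  tab <- table(factor(scores, levels = seq_len(max_score)))
  rel <- as.numeric(tab) / length(scores)
  names(rel) <- seq_len(max_score)
  structure(list(rel_time = rel[rel > 0], max_score = as.integer(max_score)),
            class = "score_time_distribution")
}

#' Relative average risk score over time
#'
#' The time-weighted mean score: the relative time in each score value
#' multiplied by that value and summed (0.3 at score 4 plus 0.7 at score 5
#' gives 4.7). Identical to the arithmetic mean of the frame-wise scores.
#'
#' @param dist a [time_distribution()], or a bare named vector of
#'   fractions (names = score values).
#' @return the time-weighted mean score.
#' @export
rel_av_rst <- function(dist) {
  rel <- if (inherits(dist, "score_time_distribution")) dist$rel_time else dist
  if (is.null(names(rel))) abort_input("distribution must name its score values")
  if (any(rel < 0) || abs(sum(rel) - 1) > 1e-9) {
    abort_input("relative times must be non-negative and sum to 1")
  }
  sum(rel * as.numeric(names(rel)))
}

#' Ergonomic risk potential (percent of the maximum possible score)
#'
#' @param rst relative average risk score over time (see [rel_av_rst()]).
#' @param max_score maximum possible score for the outcome.
#' @return ERP in percent, full precision (round at the reporting layer,
#'   half-up, to match printed tables).
#' @export
erp <- function(rst, max_score) {
  if (any(rst > max_score + 1e-9)) {
    abort_integrity("rel. av. RST exceeds the outcome's maximum score")
  }
  if (any(rst < 1 - 1e-9)) abort_input("rel. av. RST below 1")
  rst / max_score * 100
}

#' Median and interquartile distance
#'
#' Median by the standard even/odd rule (half-integers arise for even n);
#' IQD = Q3 - Q1 using linear-interpolation quantiles ([stats::quantile()]
#' type 7).
#'
#' @param values numeric vector.
#' @return named numeric vector `c(median = , iqd = )`.
#' @export
median_iqd <- function(values) {
  if (length(values) == 0) abort_input("empty value sequence")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(median = stats::median(values), iqd = q[2] - q[1])
}

#' Per-outcome risk summary for one scored recording
#'
#' For each of the nine reporting outcomes: the time distribution, its
#' rel. av. RST and ERP, and the median/IQD of the frame-wise scores.
#'
#' @param scores a `rula_scores` data.frame from [score_recording()].
#' @return data.frame with one row per outcome: `outcome`, `max_score`,
#'   `median`, `iqd`, `rel_av_rst`, `erp_pct`, plus the recording's
#'   metadata columns.
#' @export
summarize_subject <- function(scores) {
  meta <- attr(scores, "meta")
  maxima <- rula_outcome_maxima()
  rows <- lapply(rula_outcomes(), function(oc) {
    s <- outcome_series(scores, oc)
    d <- time_distribution(s, maxima[[oc]])
    rst <- rel_av_rst(d)
    mi <- median_iqd(s)
    data.frame(outcome = oc, max_score = maxima[[oc]],
               median = unname(mi["median"]), iqd = unname(mi["iqd"]),
               rel_av_rst = rst, erp_pct = erp(rst, maxima[[oc]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    out <- cbind(data.frame(subject_id = meta$subject_id,
                            occupation = meta$occupation,
                            pair_id = meta$pair_id, dwc = meta$dwc,
                            stringsAsFactors = FALSE), out)
  }
  out
}

#' Summarise a scored cohort into subject- and group-level tables
#'
#' Aggregation is per subject first: every recording yields its own
#' rel. av. RST, ERP, median and IQD per outcome; group cells (one per
#' outcome, occupation and workplace concept) then take the median/IQD of
#' the subject-level medians, the mean of the subject-level rel. av. RST
#' and its ERP.
#'
#' @param subject_summaries data.frame row-binding [summarize_subject()]
#'   outputs for the whole cohort.
#' @return data.frame with one row per (outcome, occupation, dwc):
#'   `median`, `iqd`, `rel_av_rst`, `erp_pct`, `n_subjects`.
#' @export
summarize_cohort <- function(subject_summaries) {
  need <- c("outcome", "occupation", "dwc", "median", "rel_av_rst", "max_score")
  if (!all(need %in% names(subject_summaries))) {
    abort_input("subject_summaries lacks required columns")
  }
  sp <- split(subject_summaries,
              subject_summaries[c("outcome", "occupation", "dwc")], drop = TRUE)
  rows <- lapply(sp, function(g) {
    mi <- median_iqd(g$median)
    rst <- mean(g$rel_av_rst)
    data.frame(outcome = g$outcome[1], occupation = g$occupation[1],
               dwc = g$dwc[1], max_score = g$max_score[1],
               median = unname(mi["median"]), iqd = unname(mi["iqd"]),
               rel_av_rst = rst, erp_pct = erp(rst, g$max_score[1]),
               n_subjects = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$outcome, rula_outcomes()), out$occupation, out$dwc), ]
}
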