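# Channel naming contract. Sided channels carry `_r` / `_l` suffixes; the
# time column is `t_s` (seconds). Flexion is positive, extension negative;
# wrist deviation is the absolute radial/ulnar deviation from the midline.

.sided_angle_channels <- c("upper_arm_flexion", "upper_arm_abduction",
                           "lower_arm_flexion", "wrist_flexion",
                           "wrist_deviation")
.sided_flag_channels <- c("shoulder_raise_flag", "arm_supported_flag",
                          "arm_across_midline_flag", "wrist_twist_endrange_flag")
.axial_angle_channels <- c("neck_flexion", "neck_rotation", "neck_side_bend",
                           "trunk_flexion", "trunk_rotation", "trunk_side_bend")
.axial_flag_channels <- c("trunk_supported_flag", "legs_supported_flag")

#' Channel names of the joint-angle dialect
#'
#' @param what `"angles"`, `"flags"` or `"all"`.
#' @return character vector of column names (without the time column `t_s`).
#' @export
angle_channels <- function(what = c("angles", "flags", "all")) {
  what <- match.arg(what)
  sided <- function(x) as.vector(t(outer(x, c("_r", "_l"), paste0)))
  ang <- c(sided(.sided_angle_channels), .axial_angle_channels)
  flg <- c(sided(.sided_flag_channels), .axial_flag_channels)
  switch(what, angles = ang, flags = flg, all = c(ang, flg))
}

.flag_default <- function(channel) {
  # Seated work: legs supported unless stated otherwise; all other flags off.
  if (channel == "legs_supported_flag") TRUE else FALSE
}

#' Construct a validated motion recording
#'
#' A `motion_recording` bundles a frame table (time column `t_s` plus the
#' named joint-angle and posture-flag channels) with subject metadata and a
#' sampling rate. Missing flag columns are filled with their documented
#' defaults (`legs_supported_flag = TRUE`, everything else `FALSE`).
#'
#' @param frames data.frame with column `t_s` and all angle channels; flag
#'   channels optional.
#' @param sampling_rate frames per second (Hz), > 0.
#' @param subject_id,pair_id opaque identifier strings.
#' @param occupation `"D"` (dentist) or `"DA"` (dental assistant).
#' @param dwc dental workplace concept, integer 1-4.
#' @param specialization one of `"generalist"`, `"orthodontist"`, `"oms"`,
#'   `"endodontologist"`, `"student"`.
#' @return a `motion_recording` object.
#' @export
motion_recording <- function(frames, sampling_rate,
                             subject_id = "s1", occupation = c("D", "DA"),
                             pair_id = "p1", dwc = 1L,
                             specialization = c("generalist", "orthodontist",
                                                "oms", "endodontologist",
                                                "student")) {
  occupation <- match.arg(occupation)
  specialization <- match.arg(specialization)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort_input("sampling_rate must be a single positive number")
  }
  if (!dwc %in% 1:4) abort_input("dwc must be 1, 2, 3 or 4")
  frames <- as.data.frame(frames)
  if (!"t_s" %in% names(frames)) abort_format("missing time column t_s")
  missing_ang <- setdiff(angle_channels("angles"), names(frames))
  if (length(missing_ang)) {
    abort_format(paste0("missing required channel(s): ",
                        paste(missing_ang, collapse = ", ")))
  }
  for (fc in angle_channels("flags")) {
    if (!fc %in% names(frames)) frames[[fc]] <- .flag_default(fc)
    frames[[fc]] <- as.logical(frames[[fc]])
    if (anyNA(frames[[fc]])) abort_parse(paste0("non-boolean values in ", fc))
  }
  rec <- structure(list(
    subject_id = as.character(subject_id), occupation = occupation,
    pair_id = as.character(pair_id), dwc = as.integer(dwc),
    specialization = specialization,
    sampling_rate = sampling_rate,
    frames = frames[, c("t_s", angle_channels("all")), drop = FALSE]
  ), class = "motion_recording")
  validate_recording(rec)
  rec
}

#' Validate a motion recording's invariants
#'
#' Checks that at least one frame is present, timestamps increase strictly
#' with spacing 1/sampling_rate (tolerance 1e-6 s — larger gaps are
#' integrity errors, never silently spanned), and that every angle is
#' finite and within \[-180, 180\] degrees.
#'
#' @param rec a `motion_recording`.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  fr <- rec$frames
  if (nrow(fr) < 1) abort_input("recording must contain at least one frame")
  t <- fr$t_s
  if (any(!is.finite(t))) abort_integrity("non-finite timestamps")
  if (nrow(fr) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) abort_integrity("timestamps must be strictly increasing")
    if (any(abs(dt - 1 / rec$sampling_rate) > 1e-6)) {
      abort_integrity(sprintf(
        "timestamp spacing deviates from 1/%g s by more than 1e-6 s",
        rec$sampling_rate))
    }
  }
  for (ch in angle_channels("angles")) {
    v <- fr[[ch]]
    if (any(!is.finite(v))) abort_integrity(paste0("non-finite angles in ", ch))
    if (any(v < -180 | v > 180)) {
      abort_integrity(paste0("angles outside [-180, 180] in ", ch))
    }
  }
  invisible(rec)
}

#' @export
print.motion_recording <- function(x, ...) {
  cat(sprintf(
    "<motion_recording> subject %s (%s, pair %s, DWC %d, %s)\n  %d frames @ %g Hz (%.1f s)\n",
    x$subject_id, x$occupation, x$pair_id, x$dwc, x$specialization,
    nrow(x$frames), x$sampling_rate,
    nrow(x$frames) / x$sampling_rate))
  invisible(x)
}

#' Read a joint-angle recording from delimited text
#'
#' Comma-separated UTF-8 with a header row naming the channels (see
#' [angle_channels()]); unknown extra columns are preserved in the file but
#' ignored by scoring. Metadata comes either from `metadata` or from a
#' sidecar JSON file `<path>.json` with the same field names.
#'
#' @param path CSV file path.
#' @param metadata named list with `subject_id`, `occupation`, `pair_id`,
#'   `dwc`, `specialization`, `sampling_rate`. Fields present in both the
#'   sidecar and `metadata` are taken from `metadata`.
#' @return a `motion_recording`.
#' @export
read_recording <- function(path, metadata = list()) {
  if (!file.exists(path)) abort_input(paste0("no such file: ", path))
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  meta[names(metadata)] <- metadata
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!"t_s" %in% names(raw)) abort_format("missing time column t_s")
  missing_ang <- setdiff(angle_channels("angles"), names(raw))
  if (length(missing_ang)) {
    abort_format(paste0("missing required channel(s): ",
                        paste(missing_ang, collapse = ", ")))
  }
  num_cols <- c("t_s", angle_channels("angles"))
  frames <- raw
  for (ch in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort_parse(sprintf("non-numeric value '%s' in column %s at data row %d",
                          raw[[ch]][bad[1]], ch, bad[1]))
    }
    frames[[ch]] <- v
  }
  for (fc in intersect(angle_channels("flags"), names(raw))) {
    v <- toupper(trimws(raw[[fc]]))
    lv <- v %in% c("TRUE", "T", "1")
    if (any(!v %in% c("TRUE", "T", "1", "FALSE", "F", "0"))) {
      abort_parse(paste0("non-boolean values in ", fc))
    }
    frames[[fc]] <- lv
  }
  sr <- meta$sampling_rate
  if (is.null(sr)) {
    if (nrow(frames) < 2) abort_input("sampling_rate metadata required for single-frame files")
    sr <- 1 / stats::median(diff(frames$t_s))
  }
  motion_recording(frames, sampling_rate = sr,
                   subject_id = meta$subject_id %||% "s1",
                   occupation = meta$occupation %||% "D",
                   pair_id = meta$pair_id %||% "p1",
                   dwc = meta$dwc %||% 1L,
                   specialization = meta$specialization %||% "generalist")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording in the same dialect `read_recording` consumes
#'
#' Numeric cells are printed with 17 significant digits so the text
#' round-trips bit-exactly to the original doubles; metadata goes to a
#' sidecar `<path>.json`.
#'
#' @param rec a `motion_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  fr <- rec$frames
  out <- fr
  for (ch in c("t_s", angle_channels("angles"))) {
    out[[ch]] <- vapply(fr[[ch]], function(x) formatC(x, digits = 17, format = "g"),
                        character(1))
  }
  for (fc in angle_channels("flags")) out[[fc]] <- ifelse(fr[[fc]], "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- rec[c("subject_id", "occupation", "pair_id", "dwc", "specialization",
                "sampling_rate")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Decimate a recording to a lower sampling rate
#'
#' Pure decimation: every k-th frame is kept (first frame retained), where
#' k = source rate / target rate must be a whole number. No anti-alias
#' filtering is applied — the scores are threshold functions of posture and
#' the recorded movements are slow, so filtering would only blur threshold
#' crossings. Flags travel with their frame.
#'
#' @param rec a `motion_recording`.
#' @param target_rate target sampling rate in Hz.
#' @return a `motion_recording` at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  ratio <- rec$sampling_rate / target_rate
  if (!is.finite(ratio) || abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    abort_input(sprintf(
      "source rate %g Hz is not an integer multiple of target rate %g Hz",
      rec$sampling_rate, target_rate))
  }
  k <- as.integer(round(ratio))
  out <- rec
  out$frames <- rec$frames[seq(1L, nrow(rec$frames), by = k), , drop = FALSE]
  rownames(out$frames) <- NULL
  out$sampling_rate <- target_rate
  validate_recording(out)
  out
}
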