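# Frame-wise RULA scoring. All scorers are vectorised over frames; a
# recording is scored in one pass per body side.

#' Fill derived posture flags
#'
#' Adds `arm_abducted_flag_r` / `arm_abducted_flag_l`, derived from the
#' abduction angle channels (`upper_arm_abduction_* > abduction threshold`,
#' strict inequality). Supplied flag columns are never overwritten;
#' per-frame `NA`s in a supplied column fall back to the derived value.
#'
#' @param frames a frame table (see [motion_recording()]).
#' @param cfg a [rula_config()].
#' @return `frames` with abduction flag columns filled.
#' @export
derive_flags <- function(frames, cfg = rula_config()) {
  for (side in c("r", "l")) {
    col <- paste0("arm_abducted_flag_", side)
    derived <- frames[[paste0("upper_arm_abduction_", side)]] >
      cfg$abduction_threshold_deg
    if (col %in% names(frames)) {
      supplied <- as.logical(frames[[col]])
      frames[[col]] <- ifelse(is.na(supplied), derived, supplied)
    } else {
      frames[[col]] <- derived
    }
  }
  frames
}

.running_extreme <- function(x, w, fun) {
  # running fun (pmin/pmax) over trailing windows of w elements; NA-padded head
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  m <- stats::embed(x, w)  # rows: windows ending at w..n
  c(rep(NA_real_, w - 1L), do.call(fun, as.data.frame(m)))
}

#' Muscle-use score for a score channel (worksheet steps 6 and 13)
#'
#' A frame earns the +1 muscle-use point when either
#' * static hold: every driving angle channel stayed within
#'   `hold_tolerance_deg` over the full trailing `window_s` (evaluated at
#'   1 s resolution; frames before one full window has elapsed cannot be
#'   static), or
#' * repeated action: the driving step score crossed bands at a rate of at
#'   least `repetition_threshold_per_min`, measured over the trailing
#'   window (or the available prefix, as a rate).
#'
#' @param angles numeric matrix or data.frame of driving angle channels,
#'   one row per frame.
#' @param step_scores integer step-score series driving the repetition rule.
#' @param rate sampling rate in Hz.
#' @param cfg a [static_window_config()].
#' @return integer 0/1 vector, one value per frame.
#' @export
muscle_use_score <- function(angles, step_scores, rate,
                             cfg = static_window_config()) {
  angles <- as.matrix(angles)
  n <- nrow(angles)
  if (n < 1 || length(step_scores) != n) {
    abort_input("angles and step_scores must be non-empty and the same length")
  }
  if (rate <= 0) abort_input("rate must be positive")
  fpb <- max(1L, as.integer(round(rate)))      # frames per 1 s block
  nsec <- ceiling(n / fpb)
  sec_of <- ceiling(seq_len(n) / fpb)
  w <- as.integer(round(cfg$window_s))

  static_sec <- rep(TRUE, nsec)
  pad <- nsec * fpb - n
  for (j in seq_len(ncol(angles))) {
    x <- c(angles[, j], rep(NA_real_, pad))
    xm <- matrix(x, nrow = fpb)
    bmax <- apply(xm, 2, max, na.rm = TRUE)
    bmin <- apply(xm, 2, min, na.rm = TRUE)
    if (nsec < w) { static_sec[] <- FALSE; break }
    rmax <- .running_extreme(as.numeric(bmax), w, pmax)
    rmin <- .running_extreme(as.numeric(bmin), w, pmin)
    ok <- (rmax - rmin) <= cfg$hold_tolerance_deg
    ok[is.na(ok)] <- FALSE
    static_sec <- static_sec & ok
  }
  static <- static_sec[sec_of]

  crossings <- c(0, as.integer(diff(step_scores) != 0))
  cum <- c(0, cumsum(crossings))  # cum[j + 1] = crossings up to frame j
  wf <- as.integer(round(cfg$window_s * rate))
  i <- seq_len(n)
  avail <- pmin(i - 1L, wf)
  cnt <- cum[i + 1L] - cum[i - avail + 1L]
  mins <- avail / rate / 60
  rep_rate <- ifelse(mins > 0, cnt / mins, 0)
  repeated <- rep_rate >= cfg$repetition_threshold_per_min & avail > 0

  as.integer(static | repeated)
}

# Channels whose hold drives the static rule for each score group.
.muscle_channels_a <- function(side) {
  paste0(c("upper_arm_flexion_", "lower_arm_flexion_", "wrist_flexion_"), side)
}
.muscle_channels_b <- function() c("neck_flexion", "trunk_flexion")

# Muscle-use series for both arm/wrist groups and the neck/trunk group.
# Two-pass: posture bands are scored first (muscle 0) to obtain the Table
# A/B series that drive the repetition rule.
.muscle_series <- function(frames, rate, cfg) {
  swc <- cfg$static_window
  out <- list()
  for (side in c("r", "l")) {
    pre <- .score_side(frames, side, 0L, 0L, cfg)
    out[[paste0("a_", side)]] <- muscle_use_score(
      frames[, .muscle_channels_a(side)], pre$table_a, rate, swc)
    if (side == "r") {
      out$b <- muscle_use_score(frames[, .muscle_channels_b()], pre$table_b,
                                rate, swc)
    }
  }
  out
}

.score_side <- function(frames, side, muscle_a, muscle_b, cfg) {
  s <- function(ch) frames[[paste0(ch, "_", side)]]
  ua <- score_upper_arm(s("upper_arm_flexion"),
                        abducted = s("arm_abducted_flag"),
                        shoulder_raised = s("shoulder_raise_flag"),
                        supported = s("arm_supported_flag"))
  la <- score_lower_arm(s("lower_arm_flexion"),
                        across_midline = s("arm_across_midline_flag"))
  wr <- score_wrist(s("wrist_flexion"), s("wrist_deviation"),
                    twist_endrange = s("wrist_twist_endrange_flag"), cfg = cfg)
  neck <- score_neck(frames$neck_flexion, frames$neck_rotation,
                     frames$neck_side_bend, cfg = cfg)
  trunk <- score_trunk(frames$trunk_flexion, frames$trunk_rotation,
                       frames$trunk_side_bend,
                       supported = frames$trunk_supported_flag, cfg = cfg)
  legs <- score_legs(frames$legs_supported_flag)
  ta <- table_a(ua, la, wr$wrist_posture, wr$wrist_twist)
  tb <- table_b(neck, trunk, legs)
  score_c <- ta + muscle_a + cfg$force_a
  score_d <- tb + muscle_b + cfg$force_b
  data.frame(
    t_s = frames$t_s,
    side = if (side == "r") "right" else "left",
    upper_arm = ua, lower_arm = la,
    wrist_posture = wr$wrist_posture, wrist_twist = wr$wrist_twist,
    wrist_combined = wr$wrist_combined,
    neck = neck, trunk = trunk, legs = legs,
    table_a = ta, table_b = tb,
    muscle_use_a = as.integer(muscle_a), muscle_use_b = as.integer(muscle_b),
    force_a = cfg$force_a, force_b = cfg$force_b,
    score_c = score_c, score_d = score_d,
    final = table_c(score_c, score_d),
    stringsAsFactors = FALSE
  )
}

#' Score a single frame (worksheet steps 1-15)
#'
#' Convenience scalar interface over the vectorised engine. Muscle-use and
#' force scores are supplied by the caller because they depend on history
#' and load, not on the single frame.
#'
#' @param frame one-row data.frame (or named list) of channels, as in
#'   [motion_recording()] frames.
#' @param side `"right"` or `"left"`.
#' @param muscle_a,muscle_b muscle-use scores (0/1) for the arm/wrist and
#'   neck/trunk/legs groups.
#' @param cfg a [rula_config()] (its `force_a`/`force_b` are used).
#' @return named list with every step score, `score_c`, `score_d` and the
#'   grand `final` score (1-7).
#' @export
score_frame <- function(frame, side = c("right", "left"), muscle_a = 0L,
                        muscle_b = 0L, cfg = rula_config()) {
  side <- match.arg(side)
  frame <- as.data.frame(as.list(frame))
  if (!"t_s" %in% names(frame)) frame$t_s <- 0
  frame <- derive_flags(frame, cfg)
  for (fc in angle_channels("flags")) {
    if (!fc %in% names(frame)) frame[[fc]] <- .flag_default(fc)
  }
  out <- .score_side(frame, substr(side, 1, 1), as.integer(muscle_a),
                     as.integer(muscle_b), cfg)
  as.list(out[1, setdiff(names(out), c("t_s", "side"))])
}

#' Score every frame of a recording, both body sides
#'
#' Computes the muscle-use series per score group (arm/wrist driven by that
#' side's upper-arm, lower-arm and wrist flexion plus the Table-A band
#' series; neck/trunk driven by neck and trunk flexion plus the Table-B band
#' series), then scores all frames. Deterministic given its inputs.
#'
#' @param rec a [motion_recording()].
#' @param cfg a [rula_config()].
#' @return a `rula_scores` data.frame, one row per frame per side, with the
#'   subject metadata in attribute `meta`.
#' @export
score_recording <- function(rec, cfg = rula_config()) {
  validate_recording(rec)
  frames <- derive_flags(rec$frames, cfg)
  rate <- rec$sampling_rate
  mu <- .muscle_series(frames, rate, cfg)
  res <- lapply(c("r", "l"), function(side) {
    .score_side(frames, side, mu[[paste0("a_", side)]], mu$b, cfg)
  })
  out <- rbind(res[[1]], res[[2]])
  attr(out, "meta") <- rec[c("subject_id", "occupation", "pair_id", "dwc",
                             "specialization", "sampling_rate")]
  class(out) <- c("rula_scores", "data.frame")
  out
}

#' Extract one reporting outcome from per-frame scores
#'
#' The nine reporting outcomes are the grand `final` score (worst side per
#' frame), the axial `trunk` and `neck` step scores, and the sided wrist
#' (combined steps 3 & 4), lower-arm and upper-arm step scores.
#'
#' @param scores a `rula_scores` data.frame from [score_recording()].
#' @param outcome one of `"final"`, `"trunk"`, `"neck"`, `"wrist_r"`,
#'   `"wrist_l"`, `"lower_arm_r"`, `"lower_arm_l"`, `"upper_arm_r"`,
#'   `"upper_arm_l"`.
#' @return integer score series, one value per frame.
#' @export
outcome_series <- function(scores, outcome = rula_outcomes()) {
  outcome <- match.arg(outcome)
  r <- scores[scores$side == "right", , drop = FALSE]
  l <- scores[scores$side == "left", , drop = FALSE]
  switch(outcome,
    final = pmax(r$final, l$final),
    trunk = r$trunk, neck = r$neck,
    wrist_r = r$wrist_combined, wrist_l = l$wrist_combined,
    lower_arm_r = r$lower_arm, lower_arm_l = l$lower_arm,
    upper_arm_r = r$upper_arm, upper_arm_l = l$upper_arm)
}

#' Reporting outcomes and their maximum scores
#'
#' @return character vector of outcome names (`rula_outcomes()`) or named
#'   integer vector of per-outcome score maxima (`rula_outcome_maxima()`).
#' @export
rula_outcomes <- function() {
  c("final", "trunk", "neck", "wrist_r", "wrist_l",
    "lower_arm_r", "lower_arm_l", "upper_arm_r", "upper_arm_l")
}

#' @rdname rula_outcomes
#' @export
rula_outcome_maxima <- function() {
  c(final = 7L, trunk = 6L, neck = 6L, wrist_r = 6L, wrist_l = 6L,
    lower_arm_r = 3L, lower_arm_l = 3L, upper_arm_r = 6L, upper_arm_l = 6L)
}
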