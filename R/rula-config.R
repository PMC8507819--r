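#' Static/repetition window configuration for the muscle-use score
#'
#' Operationalises the worksheet's verbal muscle-use rule ("mainly static,
#' held longer than one minute, or repeated more than 4 times per minute")
#' for continuous recordings: a frame earns the +1 when the driving posture
#' angles stayed within `hold_tolerance_deg` over the full trailing
#' `window_s`, or when the driving step score crossed bands at a rate of at
#' least `repetition_threshold_per_min` within the trailing window.
#'
#' @param window_s trailing window length in seconds (default 60).
#' @param hold_tolerance_deg maximum angle excursion (max - min, degrees)
#'   still counted as a static hold (default 5).
#' @param repetition_threshold_per_min band-crossing rate that counts as
#'   repeated action (default 4 per minute).
#' @return a `static_window_config` list.
#' @export
static_window_config <- function(window_s = 60, hold_tolerance_deg = 5,
                                 repetition_threshold_per_min = 4) {
  if (window_s <= 0 || hold_tolerance_deg <= 0 || repetition_threshold_per_min <= 0) {
    abort_config("all static-window parameters must be strictly positive")
  }
  structure(list(window_s = window_s,
                 hold_tolerance_deg = hold_tolerance_deg,
                 repetition_threshold_per_min = repetition_threshold_per_min),
            class = "static_window_config")
}

#' RULA engine configuration
#'
#' All band boundaries follow the published worksheet; thresholds the
#' worksheet leaves verbal ("twisted", "side bending", "deviated") are
#' symmetric absolute-angle thresholds, configurable here. Band boundaries
#' are closed on the lower-risk side: an angle exactly on a boundary scores
#' the milder band.
#'
#' @param wrist_neutral_band_deg half-width of the wrist "neutral" band that
#'   scores 1 (default 0: any measured flexion/extension leaves neutral, the
#'   conservative choice for continuous joint-angle data).
#' @param wrist_deviation_threshold_deg absolute radial/ulnar deviation above
#'   which the wrist score gets +1 (default 10).
#' @param neck_rotation_threshold_deg,neck_side_bend_threshold_deg absolute
#'   angles above which the neck score gets +1 each (default 10).
#' @param trunk_rotation_threshold_deg,trunk_side_bend_threshold_deg absolute
#'   angles above which the trunk score gets +1 each (default 10).
#' @param trunk_neutral_band_deg half-width of the trunk band that scores 1
#'   when seated and well supported (default 10).
#' @param abduction_threshold_deg upper-arm abduction above which the derived
#'   abduction flag turns on (default 45, strict inequality).
#' @param static_window a [static_window_config()].
#' @param force_a,force_b force/load scores (0-3) added to score C and
#'   score D (default 0: dental instruments weigh well under 2 kg and are
#'   held intermittently).
#' @return a `rula_config` list.
#' @export
rula_config <- function(wrist_neutral_band_deg = 0,
                        wrist_deviation_threshold_deg = 10,
                        neck_rotation_threshold_deg = 10,
                        neck_side_bend_threshold_deg = 10,
                        trunk_rotation_threshold_deg = 10,
                        trunk_side_bend_threshold_deg = 10,
                        trunk_neutral_band_deg = 10,
                        abduction_threshold_deg = 45,
                        static_window = static_window_config(),
                        force_a = 0L, force_b = 0L) {
  thr <- c(wrist_deviation_threshold_deg, neck_rotation_threshold_deg,
           neck_side_bend_threshold_deg, trunk_rotation_threshold_deg,
           trunk_side_bend_threshold_deg, trunk_neutral_band_deg,
           abduction_threshold_deg)
  if (any(!is.finite(thr)) || any(thr < 0) || wrist_neutral_band_deg < 0) {
    abort_config("thresholds must be finite and non-negative")
  }
  if (!all(c(force_a, force_b) %in% 0:3)) abort_config("force scores must be in 0..3")
  structure(list(
    wrist_neutral_band_deg = wrist_neutral_band_deg,
    wrist_deviation_threshold_deg = wrist_deviation_threshold_deg,
    neck_rotation_threshold_deg = neck_rotation_threshold_deg,
    neck_side_bend_threshold_deg = neck_side_bend_threshold_deg,
    trunk_rotation_threshold_deg = trunk_rotation_threshold_deg,
    trunk_side_bend_threshold_deg = trunk_side_bend_threshold_deg,
    trunk_neutral_band_deg = trunk_neutral_band_deg,
    abduction_threshold_deg = abduction_threshold_deg,
    static_window = static_window,
    force_a = as.integer(force_a), force_b = as.integer(force_b)
  ), class = "rula_config")
}
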