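# Individual worksheet steps, vectorised over frames. Sign conventions:
# flexion positive, extension negative, all angles in degrees. Band
# boundaries are closed on the lower-risk side (exactly 20 deg of upper-arm
# flexion still scores the milder band).

.check_angle <- function(x, what) {
  if (any(!is.finite(x))) abort_input(sprintf("non-finite %s angle", what))
}

.as_flag <- function(x, n, default = FALSE) {
  if (is.null(x)) return(rep(default, n))
  x <- as.logical(x)
  x[is.na(x)] <- default
  x
}

#' Upper arm score (worksheet step 1)
#'
#' Base score from shoulder flexion/extension, +1 if the shoulder is raised,
#' +1 if the upper arm is abducted, -1 if the arm is supported or the person
#' is leaning; clamped to 1-6.
#'
#' @param flexion upper-arm flexion in degrees (extension negative).
#' @param abducted,shoulder_raised,supported logical flags.
#' @return integer score 1-6, vectorised.
#' @export
score_upper_arm <- function(flexion, abducted = FALSE, shoulder_raised = FALSE,
                            supported = FALSE) {
  .check_angle(flexion, "upper-arm flexion")
  n <- length(flexion)
  base <- ifelse(flexion > 90, 4L,
          ifelse(flexion > 45, 3L,
          ifelse(flexion > 20 | flexion < -20, 2L, 1L)))
  s <- base + .as_flag(shoulder_raised, n) + .as_flag(abducted, n) -
    .as_flag(supported, n)
  as.integer(pmin(pmax(s, 1L), 6L))
}

#' Lower arm score (worksheet step 2)
#'
#' 1 when the elbow works in the 60-100 degree flexion range, 2 outside it,
#' +1 when the arm works across the midline or out to the side; clamped to 1-3.
#'
#' @param flexion lower-arm (elbow) flexion in degrees.
#' @param across_midline logical flag.
#' @return integer score 1-3, vectorised.
#' @export
score_lower_arm <- function(flexion, across_midline = FALSE) {
  .check_angle(flexion, "lower-arm flexion")
  n <- length(flexion)
  base <- ifelse(flexion >= 60 & flexion <= 100, 1L, 2L)
  as.integer(pmin(pmax(base + .as_flag(across_midline, n), 1L), 3L))
}

#' Wrist scores (worksheet steps 3 and 4, with a combined reporting score)
#'
#' Posture: 1 in the neutral band, 2 up to 15 degrees of flexion/extension,
#' 3 beyond, +1 when radial/ulnar deviation exceeds the threshold (capped at
#' 4). Twist: 1 mid-range, 2 at or near end of range. The combined wrist
#' score used for reporting is posture + twist (range 2-6), matching the
#' reported step maximum of 6.
#'
#' @param flexion wrist flexion in degrees (extension negative).
#' @param deviation absolute radial/ulnar deviation in degrees (>= 0).
#' @param twist_endrange logical flag.
#' @param cfg a [rula_config()].
#' @return list with integer vectors `wrist_posture` (1-4), `wrist_twist`
#'   (1-2) and `wrist_combined` (2-6).
#' @export
score_wrist <- function(flexion, deviation, twist_endrange = FALSE,
                        cfg = rula_config()) {
  .check_angle(flexion, "wrist flexion")
  .check_angle(deviation, "wrist deviation")
  if (any(deviation < 0)) abort_input("wrist deviation must be non-negative")
  n <- length(flexion)
  band <- cfg$wrist_neutral_band_deg
  posture <- ifelse(abs(flexion) > 15, 3L,
             ifelse(abs(flexion) > band, 2L, 1L))
  posture <- posture + (deviation > cfg$wrist_deviation_threshold_deg)
  posture <- as.integer(pmin(posture, 4L))
  twist <- as.integer(ifelse(.as_flag(twist_endrange, n), 2L, 1L))
  list(wrist_posture = posture, wrist_twist = twist,
       wrist_combined = as.integer(posture + twist))
}

#' Neck score (worksheet step 9)
#'
#' Base 1/2/3 for 0-10/10-20/>20 degrees of flexion, 4 for any extension;
#' +1 if the neck is twisted, +1 if side-bending, both judged by absolute
#' angle thresholds; clamped to 1-6.
#'
#' @param flexion neck flexion in degrees (extension negative).
#' @param rotation,side_bend neck rotation and lateral bend in degrees.
#' @param cfg a [rula_config()].
#' @return integer score 1-6, vectorised.
#' @export
score_neck <- function(flexion, rotation = 0, side_bend = 0, cfg = rula_config()) {
  .check_angle(flexion, "neck flexion")
  .check_angle(rotation, "neck rotation")
  .check_angle(side_bend, "neck side-bend")
  base <- ifelse(flexion < 0, 4L,
          ifelse(flexion > 20, 3L,
          ifelse(flexion > 10, 2L, 1L)))
  s <- base + (abs(rotation) > cfg$neck_rotation_threshold_deg) +
    (abs(side_bend) > cfg$neck_side_bend_threshold_deg)
  as.integer(pmin(s, 6L))
}

#' Trunk score (worksheet step 10)
#'
#' 1 when seated, well supported and within the neutral band; otherwise 2 up
#' to 20 degrees of flexion (and for extension beyond the neutral band), 3 up
#' to 60, 4 beyond; +1 twisted, +1 side-bending; clamped to 1-6.
#'
#' @param flexion trunk flexion in degrees (extension negative).
#' @param rotation,side_bend trunk rotation and lateral bend in degrees.
#' @param supported logical: seated with trunk well supported.
#' @param cfg a [rula_config()].
#' @return integer score 1-6, vectorised.
#' @export
score_trunk <- function(flexion, rotation = 0, side_bend = 0, supported = FALSE,
                        cfg = rula_config()) {
  .check_angle(flexion, "trunk flexion")
  .check_angle(rotation, "trunk rotation")
  .check_angle(side_bend, "trunk side-bend")
  n <- length(flexion)
  supported <- .as_flag(supported, n)
  band <- cfg$trunk_neutral_band_deg
  base <- ifelse(supported & abs(flexion) <= band, 1L,
          ifelse(flexion > 60, 4L,
          ifelse(flexion > 20, 3L, 2L)))
  s <- base + (abs(rotation) > cfg$trunk_rotation_threshold_deg) +
    (abs(side_bend) > cfg$trunk_side_bend_threshold_deg)
  as.integer(pmin(s, 6L))
}

#' Legs score (worksheet step 11)
#'
#' 1 when legs and feet are supported and balanced, 2 otherwise. Seated
#' work with both feet on the floor defaults to 1.
#'
#' @param supported logical flag (default TRUE).
#' @return integer score 1-2, vectorised.
#' @export
score_legs <- function(supported = TRUE) {
  as.integer(ifelse(.as_flag(supported, length(supported), default = TRUE), 1L, 2L))
}
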