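# Fixture builders: frame tables are generated in code, never stored.

neutral_frame_defaults <- function() {
  vals <- list(
    upper_arm_flexion_r = 0, upper_arm_flexion_l = 0,
    upper_arm_abduction_r = 0, upper_arm_abduction_l = 0,
    lower_arm_flexion_r = 80, lower_arm_flexion_l = 80,
    wrist_flexion_r = 0, wrist_flexion_l = 0,
    wrist_deviation_r = 0, wrist_deviation_l = 0,
    neck_flexion = 5, neck_rotation = 0, neck_side_bend = 0,
    trunk_flexion = 0, trunk_rotation = 0, trunk_side_bend = 0)
  flags <- as.list(stats::setNames(rep(FALSE, length(angle_channels("flags"))),
                                   angle_channels("flags")))
  flags$legs_supported_flag <- TRUE
  c(vals, flags)
}

make_frames <- function(n = 10, rate = 24, ...) {
  over <- list(...)
  cols <- neutral_frame_defaults()
  cols[names(over)] <- over
  df <- data.frame(t_s = (seq_len(n) - 1) / rate)
  for (nm in names(cols)) {
    v <- cols[[nm]]
    df[[nm]] <- if (length(v) == n) v else rep_len(v, n)
  }
  df
}

make_recording <- function(n = 10, rate = 24, ...) {
  motion_recording(make_frames(n, rate, ...), sampling_rate = rate)
}

# Random frames on a 5-degree grid over each channel's plausible range,
# flags fair coin flips: the stress-test input for oracle equivalence.
random_grid_frames <- function(n, seed = 1) {
  set.seed(seed)
  grid5 <- function(lo, hi) seq(lo, hi, by = 5)
  df <- data.frame(t_s = (seq_len(n) - 1) / 24)
  rng <- list(
    upper_arm_flexion = grid5(-60, 150), upper_arm_abduction = grid5(0, 90),
    lower_arm_flexion = grid5(0, 150), wrist_flexion = grid5(-60, 60),
    wrist_deviation = grid5(0, 40))
  for (ch in names(rng)) {
    for (side in c("_r", "_l")) {
      df[[paste0(ch, side)]] <- sample(rng[[ch]], n, replace = TRUE)
    }
  }
  axial <- list(
    neck_flexion = grid5(-40, 60), neck_rotation = grid5(-45, 45),
    neck_side_bend = grid5(-30, 30), trunk_flexion = grid5(-30, 90),
    trunk_rotation = grid5(-30, 30), trunk_side_bend = grid5(-30, 30))
  for (ch in names(axial)) df[[ch]] <- sample(axial[[ch]], n, replace = TRUE)
  for (fc in angle_channels("flags")) {
    df[[fc]] <- sample(c(TRUE, FALSE), n, replace = TRUE)
  }
  df
}
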