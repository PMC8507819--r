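test_that("step scorers reproduce the worksheet bands and adjustments", {
  # upper arm: bands closed on the lower-risk side
  expect_identical(score_upper_arm(10), 1L)
  expect_identical(score_upper_arm(20), 1L)
  expect_identical(score_upper_arm(-25), 2L)
  expect_identical(score_upper_arm(100, abducted = TRUE, shoulder_raised = TRUE), 6L)
  expect_identical(score_upper_arm(10, supported = TRUE), 1L)  # clamp at 1
  # lower arm
  expect_identical(score_lower_arm(80), 1L)
  expect_identical(score_lower_arm(100), 1L)
  expect_identical(score_lower_arm(30, across_midline = TRUE), 3L)
  # wrist: combined = posture + twist, max 6
  expect_equal(score_wrist(0, 0), list(wrist_posture = 1L, wrist_twist = 1L,
                                       wrist_combined = 2L))
  expect_equal(score_wrist(20, 12, TRUE), list(wrist_posture = 4L,
                                               wrist_twist = 2L,
                                               wrist_combined = 6L))
  expect_equal(score_wrist(-10, 0)$wrist_combined, 3L)
  # neck: extension scores 4
  expect_identical(score_neck(5), 1L)
  expect_identical(score_neck(25, 20, 15), 5L)
  expect_identical(score_neck(-5), 4L)
  # trunk: seated well-supported neutral scores 1
  expect_identical(score_trunk(0, supported = TRUE), 1L)
  expect_identical(score_trunk(30, 15, 15), 5L)
  expect_identical(score_trunk(70), 4L)
  expect_identical(score_legs(TRUE), 1L)
  expect_identical(score_legs(FALSE), 2L)
})

test_that("non-finite angles and negative deviations are input errors", {
  expect_error(score_upper_arm(NaN), class = "rula_input_error")
  expect_error(score_neck(Inf), class = "rula_input_error")
  expect_error(score_wrist(0, -1), class = "rula_input_error")
})

test_that("score_frame walks the worksheet end to end", {
  # neutral seated frame, muscle 1/1: tables A and B are both 1
  fr <- make_frames(1, trunk_supported_flag = TRUE)
  out <- score_frame(fr[1, ], "right", muscle_a = 1, muscle_b = 1)
  expect_identical(out$table_a, 1L)
  expect_identical(out$table_b, 1L)
  expect_identical(out$score_c, 2L)
  expect_identical(out$score_d, 2L)
  expect_identical(out$final, table_c(2L, 2L))
  # saturated frame
  fr <- make_frames(1, upper_arm_flexion_r = 100, upper_arm_abduction_r = 60,
                    shoulder_raise_flag_r = TRUE, lower_arm_flexion_r = 30,
                    arm_across_midline_flag_r = TRUE, wrist_flexion_r = 30,
                    wrist_deviation_r = 20, wrist_twist_endrange_flag_r = TRUE,
                    neck_flexion = 30, neck_rotation = 30, neck_side_bend = 30,
                    trunk_flexion = 70, trunk_rotation = 30,
                    trunk_side_bend = 30, legs_supported_flag = FALSE)
  out <- score_frame(fr[1, ], "right", muscle_a = 1, muscle_b = 1)
  expect_identical(out$final, 7L)
})

test_that("score_frame matches the straight-line worksheet oracle on a random 5-degree grid", {
  df <- random_grid_frames(3000, seed = 101)
  df <- derive_flags(df, rula_config())
  for (i in seq_len(nrow(df))) {
    got <- score_frame(df[i, ], "right", muscle_a = i %% 2, muscle_b = (i + 1) %% 2)
    want <- oracle_score_frame(
      df$upper_arm_flexion_r[i], df$arm_abducted_flag_r[i],
      df$shoulder_raise_flag_r[i], df$arm_supported_flag_r[i],
      df$lower_arm_flexion_r[i], df$arm_across_midline_flag_r[i],
      df$wrist_flexion_r[i], df$wrist_deviation_r[i],
      df$wrist_twist_endrange_flag_r[i],
      df$neck_flexion[i], df$neck_rotation[i], df$neck_side_bend[i],
      df$trunk_flexion[i], df$trunk_rotation[i], df$trunk_side_bend[i],
      df$trunk_supported_flag[i], df$legs_supported_flag[i],
      muscle_a = i %% 2, muscle_b = (i + 1) %% 2)
    for (f in names(want)) {
      if (!identical(as.integer(got[[f]]), as.integer(want[[f]]))) {
        fail(sprintf("field %s differs at row %d: %s vs %s", f, i,
                     got[[f]], want[[f]]))
      }
    }
  }
  succeed()
})

test_that("pushing an angle deeper into a worse band never lowers step or final scores", {
  base <- make_frames(1, neck_flexion = 5, trunk_flexion = 5,
                      wrist_flexion_r = 5, upper_arm_flexion_r = 5)
  channels <- list(
    neck_flexion = seq(0, 60, by = 5),
    trunk_flexion = seq(0, 90, by = 5),
    wrist_flexion_r = seq(0, 60, by = 5),
    upper_arm_flexion_r = seq(0, 150, by = 5),
    wrist_deviation_r = seq(0, 30, by = 5))
  for (ch in names(channels)) {
    prev_final <- -Inf
    for (v in channels[[ch]]) {
      fr <- base
      fr[[ch]] <- v
      out <- score_frame(fr[1, ], "right", muscle_a = 0, muscle_b = 0)
      expect_gte(out$final, prev_final)
      prev_final <- out$final
    }
  }
})

test_that("muscle-use static rule fires only after a full held window", {
  rate <- 24
  n <- 90 * rate
  ang <- matrix(10, n, 2)
  scores <- rep(3L, n)
  m <- muscle_use_score(ang, scores, rate)
  t_s <- (seq_len(n) - 1) / rate
  expect_true(all(m[t_s >= 60] == 1))
  expect_identical(m[1], 0L)
  # slow drift beyond tolerance with a single band change -> never muscle use
  drift <- matrix(seq(0, 15, length.out = n), n, 1)
  sc2 <- c(rep(1L, n / 2), rep(2L, n / 2))
  expect_true(all(muscle_use_score(drift, sc2, rate) == 0))
  # band alternation at 6/min triggers the repetition rule
  sc3 <- rep(rep(c(1L, 2L), each = rate * 5), length.out = n)
  m3 <- muscle_use_score(drift, sc3, rate)
  expect_true(mean(m3[t_s > 20]) > 0.95)
})

test_that("scoring a recording is deterministic and sides are independent", {
  rec <- make_recording(48, upper_arm_flexion_r = 30, wrist_flexion_l = 20)
  s1 <- score_recording(rec)
  s2 <- score_recording(rec)
  expect_identical(s1, s2)
  # perturb left-arm channels only: right-side arm scores unchanged
  rec2 <- rec
  rec2$frames$upper_arm_flexion_l <- 120
  rec2$frames$wrist_deviation_l <- 30
  s3 <- score_recording(rec2)
  right_cols <- c("upper_arm", "lower_arm", "wrist_posture", "wrist_combined",
                  "table_a")
  expect_identical(s1[s1$side == "right", right_cols],
                   s3[s3$side == "right", right_cols])
  expect_false(identical(s1[s1$side == "left", "upper_arm"],
                         s3[s3$side == "left", "upper_arm"]))
})

test_that("step maxima are respected on scored recordings (6/6/6/3, final 7)", {
  lib <- dental_posture_states()
  rec <- generate_recording(lib$states, duration_s = 30, rate = 24, seed = 5,
                            weights = lib$weights)
  sc <- score_recording(rec)
  expect_true(all(sc$upper_arm <= 6), all(sc$neck <= 6))
  expect_true(all(sc$trunk <= 6))
  expect_true(all(sc$wrist_combined <= 6))
  expect_true(all(sc$lower_arm <= 3))
  expect_true(all(sc$final >= 1 & sc$final <= 7))
})

test_that("derived abduction flags respect supplied values and strict threshold", {
  fr <- make_frames(3, upper_arm_abduction_r = c(50, 45, 0))
  out <- derive_flags(fr, rula_config())
  expect_identical(out$arm_abducted_flag_r, c(TRUE, FALSE, FALSE))
  fr$arm_abducted_flag_r <- c(NA, NA, TRUE)  # supplied flag wins where given
  out <- derive_flags(fr, rula_config())
  expect_identical(out$arm_abducted_flag_r, c(TRUE, FALSE, TRUE))
})
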