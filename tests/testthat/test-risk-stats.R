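test_that("time distributions count relative frame time exactly", {
  d <- time_distribution(c(4, 4, 4, 5, 5, 5, 5, 5, 5, 5), 7)
  expect_equal(d$rel_time, c("4" = 0.3, "5" = 0.7))
  expect_equal(sum(d$rel_time), 1, tolerance = 1e-12)
  d7 <- time_distribution(rep(7L, 50), 7)
  expect_equal(d7$rel_time, c("7" = 1))
  expect_error(time_distribution(integer(0), 7), class = "rula_input_error")
  expect_error(time_distribution(c(1, 2, 3), 2), class = "rula_integrity_error")
})

test_that("rel. av. RST is the time-weighted mean score", {
  expect_equal(rel_av_rst(c("4" = 0.3, "5" = 0.7)), 4.7)
  expect_equal(rel_av_rst(c("7" = 1)), 7)
  expect_equal(rel_av_rst(c("1" = 0.5, "7" = 0.5)), 4)
  # identity with the arithmetic mean of the raw sequence
  set.seed(42)
  for (i in 1:20) {
    s <- sample(1:7, 200, replace = TRUE, prob = runif(7))
    expect_equal(rel_av_rst(time_distribution(s, 7)), mean(s), tolerance = 1e-12)
  }
})

test_that("ERP converts rel. av. RST to percent of the outcome maximum", {
  expect_equal(round_half_up(erp(6.75, 7), 2), 96.43)
  expect_equal(erp(7, 7), 100)
  expect_equal(round_half_up(erp(1.41, 6), 2), 23.50)
  expect_error(erp(6.5, 6), class = "rula_integrity_error")
  # scale consistency: doubling the maximum halves the percentage
  expect_equal(erp(3, 6), erp(3, 3) / 2)
})

test_that("median/IQD use the even/odd rule and linear-interpolation quartiles", {
  expect_equal(median_iqd(c(7, 7, 7, 7, 6))[["median"]], 7)
  expect_equal(median_iqd(c(6, 7))[["median"]], 6.5)
  expect_equal(median_iqd(c(1, 2, 3, 4, 5))[["iqd"]], 2)
  expect_error(median_iqd(numeric(0)), class = "rula_input_error")
})

test_that("subject summaries cover all nine outcomes with their maxima", {
  rec <- make_recording(48, trunk_supported_flag = TRUE)
  ss <- summarize_subject(score_recording(rec))
  expect_setequal(ss$outcome, rula_outcomes())
  expect_equal(ss$max_score[match(rula_outcomes(), ss$outcome)],
               unname(rula_outcome_maxima()))
  expect_true(all(ss$erp_pct > 0 & ss$erp_pct <= 100))
  expect_equal(ss$erp_pct, ss$rel_av_rst / ss$max_score * 100)
  # degenerate all-frames-at-one-score case
  fr <- make_frames(24, upper_arm_flexion_r = 100, upper_arm_abduction_r = 60,
                    shoulder_raise_flag_r = TRUE, lower_arm_flexion_r = 30,
                    arm_across_midline_flag_r = TRUE, wrist_flexion_r = 30,
                    wrist_deviation_r = 20, wrist_twist_endrange_flag_r = TRUE,
                    neck_flexion = 30, neck_rotation = 30, neck_side_bend = 30,
                    trunk_flexion = 70, trunk_rotation = 30,
                    trunk_side_bend = 30, legs_supported_flag = FALSE)
  ss2 <- summarize_subject(score_recording(motion_recording(fr, 24)))
  fin <- ss2[ss2$outcome == "final", ]
  expect_equal(fin$median, 7)
  expect_equal(fin$iqd, 0)
  expect_equal(fin$rel_av_rst, 7)
  expect_equal(fin$erp_pct, 100)
})

test_that("group cells aggregate per-subject values (median/IQD, mean RST)", {
  mk <- function(subj, occ, dwc, rst, med) {
    data.frame(subject_id = subj, occupation = occ, pair_id = "p", dwc = dwc,
               outcome = "final", max_score = 7L, median = med, iqd = 0,
               rel_av_rst = rst, erp_pct = rst / 7 * 100)
  }
  ss <- rbind(mk("a", "D", 1, 6.5, 7), mk("b", "D", 1, 6.7, 7),
              mk("c", "D", 1, 6.9, 6))
  tab <- summarize_cohort(ss)
  expect_equal(tab$rel_av_rst, mean(c(6.5, 6.7, 6.9)))
  expect_equal(tab$median, 7)
  expect_equal(tab$n_subjects, 3)
  expect_equal(tab$erp_pct, tab$rel_av_rst / 7 * 100)
})
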