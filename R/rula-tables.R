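# The three RULA lookup tables (McAtamney & Corlett worksheet).
# Table A: posture score A from upper arm (1-6), lower arm (1-3),
#          wrist posture (1-4) and wrist twist (1-2).
# Table B: posture score B from neck (1-6), trunk (1-6) and legs (1-2).
# Table C: grand score (1-7) from score C (rows, saturating at 8+) and
#          score D (columns, saturating at 7+).

.rula_table_a <- local({
  a <- array(NA_integer_, dim = c(6, 3, 4, 2),
             dimnames = list(upper_arm = 1:6, lower_arm = 1:3,
                             wrist = 1:4, twist = 1:2))
  # rows: one per (upper arm, lower arm); cols: wrist 1..4 x twist 1..2
  rows <- rbind(
    c(1,2, 2,2, 2,3, 3,3),  # UA1 LA1
    c(2,2, 2,2, 3,3, 3,3),  # UA1 LA2
    c(2,3, 3,3, 3,3, 4,4),  # UA1 LA3
    c(2,3, 3,3, 3,4, 4,4),  # UA2 LA1
    c(3,3, 3,3, 3,4, 4,4),  # UA2 LA2
    c(3,4, 4,4, 4,4, 5,5),  # UA2 LA3
    c(3,3, 4,4, 4,4, 5,5),  # UA3 LA1
    c(3,4, 4,4, 4,4, 5,5),  # UA3 LA2
    c(4,4, 4,4, 4,5, 5,5),  # UA3 LA3
    c(4,4, 4,4, 4,5, 5,5),  # UA4 LA1
    c(4,4, 4,4, 4,5, 5,5),  # UA4 LA2
    c(4,4, 4,5, 5,5, 6,6),  # UA4 LA3
    c(5,5, 5,5, 5,6, 6,7),  # UA5 LA1
    c(5,6, 6,6, 6,7, 7,7),  # UA5 LA2
    c(6,6, 6,7, 7,7, 7,8),  # UA5 LA3
    c(7,7, 7,7, 7,8, 8,9),  # UA6 LA1
    c(8,8, 8,8, 8,9, 9,9),  # UA6 LA2
    c(9,9, 9,9, 9,9, 9,9)   # UA6 LA3
  )
  i <- 0L
  for (ua in 1:6) for (la in 1:3) {
    i <- i + 1L
    for (w in 1:4) for (tw in 1:2) a[ua, la, w, tw] <- rows[i, (w - 1L) * 2L + tw]
  }
  storage.mode(a) <- "integer"
  a
})

.rula_table_b <- local({
  b <- array(NA_integer_, dim = c(6, 6, 2),
             dimnames = list(neck = 1:6, trunk = 1:6, legs = 1:2))
  rows <- rbind(
    c(1,3, 2,3, 3,4, 5,5, 6,6, 7,7),  # neck 1
    c(2,3, 2,3, 4,5, 5,5, 6,7, 7,7),  # neck 2
    c(3,3, 3,4, 4,5, 5,6, 6,7, 7,7),  # neck 3
    c(5,5, 5,6, 6,7, 7,7, 7,7, 8,8),  # neck 4
    c(7,7, 7,7, 7,8, 8,8, 8,8, 8,8),  # neck 5
    c(8,8, 8,8, 8,8, 8,9, 9,9, 9,9)   # neck 6
  )
  for (n in 1:6) for (t in 1:6) for (l in 1:2) b[n, t, l] <- rows[n, (t - 1L) * 2L + l]
  storage.mode(b) <- "integer"
  b
})

.rula_table_c <- local({
  m <- rbind(
    c(1, 2, 3, 3, 4, 5, 5),
    c(2, 2, 3, 4, 4, 5, 5),
    c(3, 3, 3, 4, 4, 5, 6),
    c(3, 3, 3, 4, 5, 6, 6),
    c(4, 4, 4, 5, 6, 7, 7),
    c(4, 4, 5, 6, 6, 7, 7),
    c(5, 5, 6, 6, 7, 7, 7),
    c(5, 5, 6, 7, 7, 7, 7)  # 8+
  )
  storage.mode(m) <- "integer"
  dimnames(m) <- list(score_c = c(1:7, "8+"), score_d = c(1:6, "7+"))
  m
})

.check_idx <- function(x, lo, hi, what) {
  if (any(!is.finite(x) | x != round(x) | x < lo | x > hi)) {
    abort_input(sprintf("%s score out of range [%d, %d]", what, lo, hi))
  }
}

#' RULA Table A lookup (arm and wrist posture score)
#'
#' Vectorised exact lookup in the worksheet's Table A.
#'
#' @param upper_arm integer 1-6.
#' @param lower_arm integer 1-3.
#' @param wrist_posture integer 1-4.
#' @param wrist_twist integer 1-2.
#' @return integer posture score A in 1-9.
#' @export
table_a <- function(upper_arm, lower_arm, wrist_posture, wrist_twist) {
  .check_idx(upper_arm, 1L, 6L, "upper arm")
  .check_idx(lower_arm, 1L, 3L, "lower arm")
  .check_idx(wrist_posture, 1L, 4L, "wrist posture")
  .check_idx(wrist_twist, 1L, 2L, "wrist twist")
  .rula_table_a[cbind(upper_arm, lower_arm, wrist_posture, wrist_twist)]
}

#' RULA Table B lookup (neck, trunk and legs posture score)
#'
#' @param neck integer 1-6.
#' @param trunk integer 1-6.
#' @param legs integer 1-2.
#' @return integer posture score B in 1-9.
#' @export
table_b <- function(neck, trunk, legs) {
  .check_idx(neck, 1L, 6L, "neck")
  .check_idx(trunk, 1L, 6L, "trunk")
  .check_idx(legs, 1L, 2L, "legs")
  .rula_table_b[cbind(neck, trunk, legs)]
}

#' RULA Table C lookup (grand score)
#'
#' Rows at or above 8 use the worksheet's "8+" band, columns at or above 7
#' the "7+" band, so the grand score saturates at 7.
#'
#' @param score_c integer >= 1 (posture score A + muscle use + force).
#' @param score_d integer >= 1 (posture score B + muscle use + force).
#' @return integer grand score in 1-7.
#' @export
table_c <- function(score_c, score_d) {
  if (any(!is.finite(score_c) | score_c < 1 | score_c != round(score_c)) ||
      any(!is.finite(score_d) | score_d < 1 | score_d != round(score_d))) {
    abort_input("score_c and score_d must be integers >= 1")
  }
  .rula_table_c[cbind(pmin(score_c, 8L), pmin(score_d, 7L))]
}
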