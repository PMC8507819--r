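# Independent straight-line transcription of the RULA worksheet, evaluated
# cell by cell with scalar if/else logic and its own copies of the lookup
# tables in long form. Deliberately written without reference to the
# package's vectorised implementation so the two can disagree.

oracle_tables <- local({
  # Table A in long form: upper arm, lower arm, wrist, twist, score
  ta <- expand.grid(ua = 1:6, la = 1:3, w = 1:4, t = 1:2)
  ta_scores <- list(
    # [ua][[la]] = c(w1t1, w1t2, w2t1, w2t2, w3t1, w3t2, w4t1, w4t2)
    list(c(1,2,2,2,2,3,3,3), c(2,2,2,2,3,3,3,3), c(2,3,3,3,3,3,4,4)),
    list(c(2,3,3,3,3,4,4,4), c(3,3,3,3,3,4,4,4), c(3,4,4,4,4,4,5,5)),
    list(c(3,3,4,4,4,4,5,5), c(3,4,4,4,4,4,5,5), c(4,4,4,4,4,5,5,5)),
    list(c(4,4,4,4,4,5,5,5), c(4,4,4,4,4,5,5,5), c(4,4,4,5,5,5,6,6)),
    list(c(5,5,5,5,5,6,6,7), c(5,6,6,6,6,7,7,7), c(6,6,6,7,7,7,7,8)),
    list(c(7,7,7,7,7,8,8,9), c(8,8,8,8,8,9,9,9), c(9,9,9,9,9,9,9,9)))
  ta$score <- mapply(function(ua, la, w, t) ta_scores[[ua]][[la]][(w - 1) * 2 + t],
                     ta$ua, ta$la, ta$w, ta$t)
  tb <- expand.grid(n = 1:6, tr = 1:6, l = 1:2)
  tb_scores <- list(
    c(1,3,2,3,3,4,5,5,6,6,7,7), c(2,3,2,3,4,5,5,5,6,7,7,7),
    c(3,3,3,4,4,5,5,6,6,7,7,7), c(5,5,5,6,6,7,7,7,7,7,8,8),
    c(7,7,7,7,7,8,8,8,8,8,8,8), c(8,8,8,8,8,8,8,9,9,9,9,9))
  tb$score <- mapply(function(n, tr, l) tb_scores[[n]][(tr - 1) * 2 + l],
                     tb$n, tb$tr, tb$l)
  tc <- rbind(c(1,2,3,3,4,5,5), c(2,2,3,4,4,5,5), c(3,3,3,4,4,5,6),
              c(3,3,3,4,5,6,6), c(4,4,4,5,6,7,7), c(4,4,5,6,6,7,7),
              c(5,5,6,6,7,7,7), c(5,5,6,7,7,7,7))
  list(a = ta, b = tb, c = tc)
})

oracle_lookup_a <- function(ua, la, w, t) {
  tab <- oracle_tables$a
  tab$score[tab$ua == ua & tab$la == la & tab$w == w & tab$t == t]
}
oracle_lookup_b <- function(n, tr, l) {
  tab <- oracle_tables$b
  tab$score[tab$n == n & tab$tr == tr & tab$l == l]
}
oracle_lookup_c <- function(sc, sd) {
  oracle_tables$c[min(sc, 8), min(sd, 7)]
}

# Scalar worksheet walk-through for one frame and one side.
oracle_score_frame <- function(ua_flex, abducted, raised, arm_supported,
                               la_flex, across,
                               wr_flex, wr_dev, twist_end,
                               neck_flex, neck_rot, neck_side,
                               trunk_flex, trunk_rot, trunk_side,
                               trunk_supported, legs_supported,
                               muscle_a = 0, muscle_b = 0,
                               force_a = 0, force_b = 0) {
  # step 1
  if (ua_flex >= -20 && ua_flex <= 20) ua <- 1
  else if (ua_flex <= 45) ua <- 2
  else if (ua_flex <= 90) ua <- 3
  else ua <- 4
  if (ua_flex < -20) ua <- 2
  if (raised) ua <- ua + 1
  if (abducted) ua <- ua + 1
  if (arm_supported) ua <- ua - 1
  ua <- min(max(ua, 1), 6)
  # step 2
  la <- if (la_flex >= 60 && la_flex <= 100) 1 else 2
  if (across) la <- la + 1
  la <- min(la, 3)
  # steps 3-4
  if (wr_flex == 0) wp <- 1
  else if (abs(wr_flex) <= 15) wp <- 2
  else wp <- 3
  if (wr_dev > 10) wp <- wp + 1
  wt <- if (twist_end) 2 else 1
  # step 9
  if (neck_flex < 0) nk <- 4
  else if (neck_flex <= 10) nk <- 1
  else if (neck_flex <= 20) nk <- 2
  else nk <- 3
  if (abs(neck_rot) > 10) nk <- nk + 1
  if (abs(neck_side) > 10) nk <- nk + 1
  nk <- min(nk, 6)
  # step 10
  if (trunk_supported && abs(trunk_flex) <= 10) tr <- 1
  else if (trunk_flex > 60) tr <- 4
  else if (trunk_flex > 20) tr <- 3
  else tr <- 2
  if (abs(trunk_rot) > 10) tr <- tr + 1
  if (abs(trunk_side) > 10) tr <- tr + 1
  tr <- min(tr, 6)
  lg <- if (legs_supported) 1 else 2
  sc <- oracle_lookup_a(ua, la, wp, wt) + muscle_a + force_a
  sd <- oracle_lookup_b(nk, tr, lg) + muscle_b + force_b
  list(upper_arm = ua, lower_arm = la, wrist_posture = wp, wrist_twist = wt,
       wrist_combined = wp + wt, neck = nk, trunk = tr, legs = lg,
       score_c = sc, score_d = sd, final = oracle_lookup_c(sc, sd))
}
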