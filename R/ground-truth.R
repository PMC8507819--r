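# Closed-form expected step scores per posture state. Given the noise model
# (independent Gaussian offset + jitter per channel), each scorer is a
# threshold function, so per-channel band probabilities are Gaussian tail
# areas and joint step-score distributions are products — an independent
# probability oracle for the engine, and the "implied expected rel. av. RST"
# entry of the synthetic ground-truth ledger.

.pint <- function(mu, sigma, lo, hi) {
  # P(lo < X <= hi), X ~ N(mu, sigma); sigma 0 degenerates to an indicator
  if (sigma <= 0) return(as.numeric(mu > lo & mu <= hi))
  stats::pnorm(hi, mu, sigma) - stats::pnorm(lo, mu, sigma)
}
.pgt <- function(mu, sigma, thr) {
  if (sigma <= 0) return(as.numeric(mu > thr))
  stats::pnorm(thr, mu, sigma, lower.tail = FALSE)
}
.pabs_gt <- function(mu, sigma, thr) 1 - .pint(mu, sigma, -thr, thr)

.mix_adjust <- function(base_dist, add_probs, max_score, min_score = 1) {
  # distribute base score + sum of independent Bernoulli add-ons (+1 each),
  # clamped to [min_score, max_score]; add_probs may include -1 entries as
  # negative Bernoullis via list(p = , delta = )
  out <- numeric(max_score)
  combos <- expand.grid(lapply(add_probs, function(a) 0:1))
  if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
  for (ci in seq_len(nrow(combos))) {
    pc <- 1
    delta <- 0
    for (j in seq_along(add_probs)) {
      on <- combos[ci, j] == 1
      pc <- pc * if (on) add_probs[[j]]$p else 1 - add_probs[[j]]$p
      if (on) delta <- delta + add_probs[[j]]$delta
    }
    for (b in seq_along(base_dist)) {
      if (base_dist[b] <= 0) next
      v <- min(max(b + delta, min_score), max_score)
      out[v] <- out[v] + base_dist[b] * pc
    }
  }
  out
}

.onehot <- function(v, len) { out <- numeric(len); out[v] <- 1; out }

# Per-state distributions of every step score under the noise model.
# With zero noise the base-band distributions come straight from the engine
# scorers, so boundary conventions agree exactly.
state_score_dists <- function(state, cfg = rula_config()) {
  m <- state$mean_angles
  fp <- state$flag_probs
  s <- sqrt(state$angle_sd^2 + state$jitter_sd^2)
  bern <- function(p, delta = 1) list(p = p, delta = delta)

  side_dists <- function(sd_suffix) {
    g <- function(ch) m[[paste0(ch, sd_suffix)]]
    f <- function(ch) fp[[paste0(ch, sd_suffix)]]
    ua_base <- if (s <= 0) {
      .onehot(score_upper_arm(g("upper_arm_flexion")), 4)
    } else {
      c(.pint(g("upper_arm_flexion"), s, -20, 20),
        .pint(g("upper_arm_flexion"), s, -Inf, -20) +
          .pint(g("upper_arm_flexion"), s, 20, 45),
        .pint(g("upper_arm_flexion"), s, 45, 90),
        .pgt(g("upper_arm_flexion"), s, 90))
    }
    ua <- .mix_adjust(c(ua_base, 0, 0),
                      list(bern(f("shoulder_raise_flag")),
                           bern(.pgt(g("upper_arm_abduction"), s,
                                     cfg$abduction_threshold_deg)),
                           bern(f("arm_supported_flag"), delta = -1)),
                      max_score = 6)
    p_in <- if (s <= 0) as.numeric(score_lower_arm(g("lower_arm_flexion")) == 1L)
            else .pint(g("lower_arm_flexion"), s, 60, 100)
    la <- .mix_adjust(c(p_in, 1 - p_in, 0),
                      list(bern(f("arm_across_midline_flag"))), max_score = 3)
    wp_base <- if (s <= 0) {
      .onehot(score_wrist(g("wrist_flexion"), 0, cfg = cfg)$wrist_posture, 3)
    } else {
      band <- cfg$wrist_neutral_band_deg
      q1 <- 1 - .pabs_gt(g("wrist_flexion"), s, band)
      q3 <- .pabs_gt(g("wrist_flexion"), s, 15)
      c(q1, max(0, 1 - q1 - q3), q3)
    }
    pd <- .pgt(g("wrist_deviation"), s, cfg$wrist_deviation_threshold_deg)
    wp <- .mix_adjust(c(wp_base, 0), list(bern(pd)), max_score = 4)
    wt <- c(1 - f("wrist_twist_endrange_flag"), f("wrist_twist_endrange_flag"))
    list(ua = ua, la = la, wp = wp, wt = wt)
  }

  neck_base <- if (s <= 0) {
    .onehot(score_neck(m[["neck_flexion"]], 0, 0, cfg = cfg), 4)
  } else {
    c(.pint(m[["neck_flexion"]], s, 0, 10),
      .pint(m[["neck_flexion"]], s, 10, 20),
      .pgt(m[["neck_flexion"]], s, 20),
      .pint(m[["neck_flexion"]], s, -Inf, 0))
  }
  neck <- .mix_adjust(c(neck_base, 0, 0),
                      list(bern(.pabs_gt(m[["neck_rotation"]], s,
                                         cfg$neck_rotation_threshold_deg)),
                           bern(.pabs_gt(m[["neck_side_bend"]], s,
                                         cfg$neck_side_bend_threshold_deg))),
                      max_score = 6)

  p_ts <- fp[["trunk_supported_flag"]]
  tf <- m[["trunk_flexion"]]
  trunk_base <- if (s <= 0) {
    p_ts * .onehot(score_trunk(tf, 0, 0, TRUE, cfg = cfg), 4) +
      (1 - p_ts) * .onehot(score_trunk(tf, 0, 0, FALSE, cfg = cfg), 4)
  } else {
    tb <- cfg$trunk_neutral_band_deg
    e1 <- 1 - .pabs_gt(tf, s, tb)
    e2 <- .pgt(tf, s, 60)
    e3 <- .pint(tf, s, 20, 60)
    e4 <- max(0, 1 - e1 - e2 - e3)
    p_ts * c(e1, e4, e3, e2) + (1 - p_ts) * c(0, e1 + e4, e3, e2)
  }
  trunk <- .mix_adjust(c(trunk_base, 0, 0),
                       list(bern(.pabs_gt(m[["trunk_rotation"]], s,
                                          cfg$trunk_rotation_threshold_deg)),
                            bern(.pabs_gt(m[["trunk_side_bend"]], s,
                                          cfg$trunk_side_bend_threshold_deg))),
                       max_score = 6)
  legs <- c(fp[["legs_supported_flag"]], 1 - fp[["legs_supported_flag"]])

  list(r = side_dists("_r"), l = side_dists("_l"),
       neck = neck, trunk = trunk, legs = legs)
}

.dist_table_a <- function(d) {
  grid <- expand.grid(ua = 1:6, la = 1:3, wp = 1:4, wt = 1:2)
  p <- d$ua[grid$ua] * d$la[grid$la] * d$wp[grid$wp] * d$wt[grid$wt]
  ta <- table_a(grid$ua, grid$la, grid$wp, grid$wt)
  as.numeric(tapply(p, factor(ta, levels = 1:9), sum, default = 0))
}

.dist_table_b <- function(dists) {
  grid <- expand.grid(n = 1:6, t = 1:6, l = 1:2)
  p <- dists$neck[grid$n] * dists$trunk[grid$t] * dists$legs[grid$l]
  tb <- table_b(grid$n, grid$t, grid$l)
  as.numeric(tapply(p, factor(tb, levels = 1:9), sum, default = 0))
}

#' Expected step scores per posture state (closed form)
#'
#' Computes, for each state in a library, the exact distribution of every
#' step score under the generator's Gaussian noise model, and from it the
#' expected value of each reporting outcome. The grand score expectation is
#' tabulated against the three muscle-use indicators (right arm, left arm,
#' neck/trunk), which depend on hold history rather than the single frame.
#'
#' @param states list of [posture_state()].
#' @param cfg a [rula_config()].
#' @return list per state: `steps` (named expected outcome values) and
#'   `final` (2 x 2 x 2 array of expected grand score by muscle indicators
#'   `[ma_r + 1, ma_l + 1, mb + 1]`).
#' @export
state_expected_scores <- function(states, cfg = rula_config()) {
  lapply(states, function(st) {
    d <- state_score_dists(st, cfg)
    ta_r <- .dist_table_a(d$r)
    ta_l <- .dist_table_a(d$l)
    tb <- .dist_table_b(d)
    wrist_dist <- function(sd) {
      out <- numeric(6)
      for (a in 1:4) for (b in 1:2) {
        out[a + b] <- out[a + b] + sd$wp[a] * sd$wt[b]
      }
      out
    }
    ev <- function(p) sum(p * seq_along(p))
    steps <- c(
      trunk = ev(d$trunk), neck = ev(d$neck),
      wrist_r = ev(wrist_dist(d$r)), wrist_l = ev(wrist_dist(d$l)),
      lower_arm_r = ev(d$r$la), lower_arm_l = ev(d$l$la),
      upper_arm_r = ev(d$r$ua), upper_arm_l = ev(d$l$ua))
    fin <- array(0, dim = c(2, 2, 2))
    grid <- expand.grid(tar = 1:9, tal = 1:9, tbv = 1:9)
    pjoint <- ta_r[grid$tar] * ta_l[grid$tal] * tb[grid$tbv]
    keep <- pjoint > 0
    grid <- grid[keep, ]; pjoint <- pjoint[keep]
    for (ma_r in 0:1) for (ma_l in 0:1) for (mb in 0:1) {
      fr <- table_c(grid$tar + ma_r + cfg$force_a, grid$tbv + mb + cfg$force_b)
      fl <- table_c(grid$tal + ma_l + cfg$force_a, grid$tbv + mb + cfg$force_b)
      fin[ma_r + 1, ma_l + 1, mb + 1] <- sum(pjoint * pmax(fr, fl))
    }
    list(steps = steps, final = fin)
  })
}

#' Implied expected rel. av. RST for one generated recording
#'
#' Combines the recording's realized state occupancy (frame-by-frame, from
#' the generator's `state_seq` attribute) with the closed-form per-state
#' expected scores. The grand score uses the muscle-use indicators the
#' engine would produce on the noiseless designed trajectory (state means
#' with the realized flags).
#'
#' @param rec a recording from [generate_recording()] (with `state_seq`).
#' @param states the state library that generated it.
#' @param expected output of [state_expected_scores()] for the same library
#'   and config (recomputed when `NULL`).
#' @param cfg a [rula_config()].
#' @return list with `expected_rst` (named per outcome), `occupancy`
#'   (fraction of frames per state).
#' @export
recording_ground_truth <- function(rec, states, expected = NULL,
                                   cfg = rula_config()) {
  seq <- attr(rec, "state_seq")
  if (is.null(seq)) abort_input("recording carries no designed state sequence")
  if (is.null(expected)) expected <- state_expected_scores(states, cfg)
  n <- length(seq)

  # noiseless trajectory: state means + realized flags -> muscle indicators
  ideal <- rec$frames
  mean_mat <- t(vapply(states, `[[`,
                       numeric(length(angle_channels("angles"))), "mean_angles"))
  for (ci in seq_along(angle_channels("angles"))) {
    ideal[[angle_channels("angles")[ci]]] <- mean_mat[seq, ci]
  }
  ideal <- derive_flags(ideal, cfg)
  mu <- .muscle_series(ideal, rec$sampling_rate, cfg)

  step_names <- setdiff(rula_outcomes(), "final")
  e_steps <- vapply(expected, function(e) e$steps[step_names],
                    numeric(length(step_names)))
  rst <- rowMeans(e_steps[, seq, drop = FALSE])
  names(rst) <- step_names
  fin_idx <- cbind(seq, mu$a_r + 1L, mu$a_l + 1L, mu$b + 1L)
  e_fin <- vapply(seq_len(n), function(i) {
    expected[[fin_idx[i, 1]]]$final[fin_idx[i, 2], fin_idx[i, 3], fin_idx[i, 4]]
  }, numeric(1))
  rst <- c(final = mean(e_fin), rst)

  occ <- as.numeric(table(factor(seq, levels = seq_along(states)))) / n
  names(occ) <- vapply(states, `[[`, "", "label")
  list(expected_rst = rst[rula_outcomes()], occupancy = occ)
}
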