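test_that("Friedman statistic: perfect concordance, all ties, and base-R agreement", {
  x <- t(replicate(10, sort(rnorm(4))))
  f <- friedman_rank_test(x)
  expect_equal(f$chi2, 30)  # n (k - 1) at perfect concordance
  x0 <- matrix(5, 4, 4)
  f0 <- friedman_rank_test(x0)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$p, 1)
  # untied data: agrees with stats::friedman.test exactly
  set.seed(7)
  for (i in 1:10) {
    x <- matrix(rnorm(60), 15, 4)
    f <- friedman_rank_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(f$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(f$p, unname(ref$p.value), tolerance = 1e-12)
  }
  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "rula_input_error")
})

test_that("exact Friedman p matches brute-force permutation enumeration (n <= 8 obs)", {
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(sample(1:12, 8), 2, 4)  # 2 subjects x 4 conditions
    expect_equal(friedman_rank_test(x, exact = TRUE)$p, brute_friedman_p(x),
                 tolerance = 1e-12)
  }
  x <- matrix(sample(1:8, 8), 4, 2)  # 4 subjects x 2 conditions
  expect_equal(friedman_rank_test(x, exact = TRUE)$p, brute_friedman_p(x),
               tolerance = 1e-12)
})

test_that("Conover-Iman statistics match a hand rank-sum calculation and are antisymmetric", {
  # 4 subjects x 4 conditions, untied: hand-computable rank sums
  x <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(1, 3, 2, 4), c(1, 2, 4, 3))
  r <- t(apply(x, 1, rank))
  Rj <- colSums(r)            # 5 8 13 14
  expect_equal(Rj, c(5, 8, 13, 14))
  A <- sum(r^2)               # 4 * 30 = 120
  B <- sum(Rj^2) / 4
  se <- sqrt(2 * 4 * (A - B) / (3 * 3))
  ci <- conover_iman(x)
  expect_equal(ci$statistic[ci$first == "cond1" & ci$second == "cond2"],
               (5 - 8) / se)
  expect_equal(ci$statistic[ci$first == "cond3" & ci$second == "cond4"],
               (13 - 14) / se)
  expect_equal(ci$p_raw[1], 2 * pt(abs((5 - 8) / se), 9, lower.tail = FALSE))
  # antisymmetry via column swap
  x2 <- x[, c(2, 1, 3, 4)]
  ci2 <- conover_iman(x2)
  expect_equal(ci2$statistic[ci2$first == "cond1" & ci2$second == "cond2"],
               -ci$statistic[ci$first == "cond1" & ci$second == "cond2"])
  # identical conditions: statistic 0, p 1
  x3 <- cbind(x, x[, 4])
  ci3 <- conover_iman(x3)
  row <- ci3[ci3$first == "cond4" & ci3$second == "cond5", ]
  expect_equal(row$statistic, 0)
  expect_equal(row$p_raw, 1)
})

test_that("Holm adjustment reproduces the step-down sequence and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0, 0, 0)), c(0, 0, 0))
  set.seed(3)
  p <- runif(9)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  expect_true(all(holm_adjust(p) >= p))
  # order invariance
  o <- sample(9)
  expect_equal(holm_adjust(p)[o], holm_adjust(p[o]))
  expect_error(holm_adjust(c(0.5, 1.2)), class = "rula_input_error")
})

test_that("Mann-Whitney U: extremes, exact enumeration, and wilcox.test agreement", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, brute_mw_p(c(1, 2, 3), c(4, 5, 6)))
  # identical groups: p 1 up to discreteness
  mwi <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(mwi$p, 0.9)
  # exact p equals brute force on random small samples, ties included
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:6, sample(2:4, 1), replace = TRUE)
    b <- sample(1:6, sample(2:4, 1), replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p, brute_mw_p(a, b), tolerance = 1e-12)
  }
  # untied exact case agrees with wilcox.test's exact distribution
  set.seed(9)
  for (i in 1:10) {
    a <- sample(seq(0, 1, by = 0.001), 5)
    b <- sample(seq(2, 3, by = 0.001), 6)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, unname(ref$statistic))
    expect_equal(mann_whitney_u(a, b)$p, ref$p.value, tolerance = 1e-9)
  }
  # large-sample normal approximation tracks wilcox.test with correction
  set.seed(13)
  a <- rnorm(30); b <- rnorm(35, 0.5)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mann_whitney_u(a, b)$p, ref$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1), class = "rula_input_error")
})

test_that("compare_dwcs gates on Friedman, adjusts within outcome, and names the lower-risk concept", {
  set.seed(21)
  mk <- function(subj, dwc, rst) {
    data.frame(subject_id = subj, occupation = "D", pair_id = subj, dwc = dwc,
               outcome = "final", max_score = 7L, median = 7, iqd = 0,
               rel_av_rst = rst, erp_pct = rst / 7 * 100)
  }
  rows <- list()
  for (s in 1:12) {
    base <- rnorm(1, 6.5, 0.05)
    for (d in 1:4) {
      shift <- if (d == 4) -0.3 else 0
      rows[[length(rows) + 1]] <- mk(sprintf("s%02d", s), d,
                                     base + shift + rnorm(1, 0, 0.03))
    }
  }
  cmp <- compare_dwcs(do.call(rbind, rows), "D")
  expect_equal(nrow(cmp), 6)
  hits <- cmp[grepl("DWC4", cmp$contrast), ]
  expect_true(all(hits$favored == "DWC4"))
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  # single-subject cohort refuses comparisons
  expect_error(compare_dwcs(do.call(rbind, lapply(1:4, function(d)
    mk("only", d, 6.5))), "D"), class = "rula_input_error")
})

test_that("compare_occupations flags a designed occupation gap in the right direction", {
  set.seed(22)
  rows <- list()
  for (s in 1:10) {
    for (occ in c("D", "DA")) {
      for (d in 1:4) {
        for (oc in c("final", "neck")) {
          mu <- if (oc == "neck" && occ == "D" && d == 4) 3.0 else 3.6
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = paste0(tolower(occ), s), occupation = occ,
            pair_id = paste0("p", s), dwc = d, outcome = oc, max_score = 6L,
            median = 3, iqd = 1, rel_av_rst = rnorm(1, mu, 0.1),
            erp_pct = mu / 6 * 100)
        }
      }
    }
  }
  res <- compare_occupations(do.call(rbind, rows))
  hit <- res[res$dwc == 4 & res$outcome == "neck" & res$measure == "rel_av_rst", ]
  expect_equal(hit$favored, "D")
  null_rows <- res[!(res$dwc == 4 & res$outcome == "neck"), ]
  expect_true(mean(null_rows$favored == "none") > 0.8)
})
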