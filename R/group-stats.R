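# Comparison design: Friedman across the four workplace concepts with
# Conover-Iman post-hoc and Bonferroni-Holm correction (within-occupation),
# Mann-Whitney U between occupations per concept (Holm across outcomes).

.check_block_matrix <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) abort_input("block matrix must have no missing cells")
  if (nrow(x) < 2) abort_input("need at least 2 subjects (blocks)")
  if (ncol(x) < 2) abort_input("need at least 2 conditions")
  x
}

#' Friedman rank test for related samples
#'
#' Within-subject mid-ranks, tie-corrected chi-square statistic
#' \eqn{(k-1) \sum_j (R_j - n(k+1)/2)^2 / (A - n k (k+1)^2 / 4)} with
#' \eqn{A = \sum r_{ij}^2}, referred to chi-square with k-1 degrees of
#' freedom. `exact = TRUE` replaces the asymptotic p with full enumeration
#' over all (k!)^n within-block rank permutations (small cohorts only).
#'
#' @param block_matrix numeric matrix, subjects in rows, conditions in
#'   columns, no missing cells.
#' @param exact logical; enumerate the permutation null instead of the
#'   chi-square approximation.
#' @return list with `chi2`, `df`, `p`, the column rank sums `rank_sums`
#'   and the rank matrix.
#' @export
friedman_rank_test <- function(block_matrix, exact = FALSE) {
  x <- .check_block_matrix(block_matrix)
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  denom <- A - n * k * (k + 1)^2 / 4
  chi2 <- if (denom <= 0) 0 else (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  if (exact) {
    if (factorial(k)^n > 2e5) abort_input("exact Friedman enumeration too large")
    perms <- .permutations(k)
    stat_of <- function(rmat) {
      Rj <- colSums(rmat)
      A <- sum(rmat^2)
      d <- A - n * k * (k + 1)^2 / 4
      if (d <= 0) 0 else (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / d
    }
    idx <- rep(1L, n)
    m <- nrow(perms)
    total <- m^n
    count <- 0L
    rmat <- r
    for (code in 0:(total - 1)) {
      c0 <- code
      for (b in seq_len(n)) {
        idx[b] <- c0 %% m + 1L
        c0 <- c0 %/% m
        rmat[b, ] <- r[b, perms[idx[b], ]]
      }
      if (stat_of(rmat) >= chi2 - 1e-12) count <- count + 1L
    }
    p <- count / total
  } else {
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  list(chi2 = chi2, df = df, p = p, rank_sums = Rj, ranks = r)
}

.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 0L
  for (i in seq_len(k)) {
    for (s in seq_len(nrow(sub))) {
      row <- row + 1L
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[s, ]])
    }
  }
  out
}

#' Conover-Iman post-hoc comparisons after a Friedman test
#'
#' Pairwise t statistics on Friedman rank sums,
#' \eqn{t = (R_i - R_j) / \sqrt{2 n (A - B) / ((n-1)(k-1))}} with
#' \eqn{A = \sum r_{ij}^2}, \eqn{B = \sum_j R_j^2 / n}, referred to the t
#' distribution with (n-1)(k-1) degrees of freedom, two-sided.
#'
#' @param block_matrix as in [friedman_rank_test()].
#' @return data.frame with one row per condition pair: `first`, `second`,
#'   `statistic` (positive when `first` has the larger rank sum), `p_raw`.
#' @export
conover_iman <- function(block_matrix) {
  x <- .check_block_matrix(block_matrix)
  n <- nrow(x); k <- ncol(x)
  df <- (n - 1) * (k - 1)
  if (df < 1) abort_input("too few subjects for Conover-Iman degrees of freedom")
  fr <- friedman_rank_test(x)
  Rj <- fr$rank_sums
  A <- sum(fr$ranks^2)
  B <- sum(Rj^2) / n
  se2 <- 2 * n * (A - B) / df
  cn <- colnames(x) %||% paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    stat <- if (se2 <= 0) 0 else (Rj[i] - Rj[j]) / sqrt(se2)
    p <- if (se2 <= 0 && Rj[i] == Rj[j]) 1
         else if (se2 <= 0) 0
         else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    data.frame(first = cn[i], second = cn[j], statistic = unname(stat),
               p_raw = min(p, 1), stringsAsFactors = FALSE)
  }))
  out
}

#' Bonferroni-Holm step-down adjustment
#'
#' The i-th smallest p-value is multiplied by (m - i + 1), a running
#' maximum enforces monotonicity and results are capped at 1, returned in
#' input order (delegates to [stats::p.adjust()], whose definition this is).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort_input("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Mann-Whitney U test for two independent groups
#'
#' U from rank sums with mid-ranks. For combined n of 12 or fewer the
#' two-sided p comes from exhaustive enumeration of all group labelings
#' (valid under ties); otherwise from the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `U` (for `group_a`), `p`, and `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) abort_input("both groups must be non-empty")
  na <- length(group_a); nb <- length(group_b); N <- na + nb
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (N <= 12) {
    combos <- utils::combn(N, na)
    us <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
    p <- 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9))
    list(U = U, p = min(p, 1), method = "exact enumeration")
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    if (sigma == 0) return(list(U = U, p = 1, method = "normal approximation"))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

.block_matrix_from_summaries <- function(summaries, value_col) {
  subj <- sort(unique(summaries$subject_id))
  dwcs <- sort(unique(summaries$dwc))
  m <- matrix(NA_real_, length(subj), length(dwcs),
              dimnames = list(subj, paste0("DWC", dwcs)))
  m[cbind(match(summaries$subject_id, subj),
          match(summaries$dwc, dwcs))] <- summaries[[value_col]]
  m
}

#' Compare the four workplace concepts within one occupation
#'
#' Per outcome: Friedman gate at `alpha` on the subjects x concepts matrix
#' of rel. av. RST values, Conover-Iman pairwise contrasts with Holm
#' correction across the outcome's 6 contrasts (computed unconditionally,
#' reported with the gate). `favored` names the concept with the lower mean
#' rel. av. RST when the adjusted p passes both the gate and `alpha`.
#'
#' @param subject_summaries row-bound [summarize_subject()] outputs.
#' @param occupation `"D"` or `"DA"`.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (outcome, contrast): statistic, raw
#'   and Holm-adjusted p, Friedman gate chi-square and p, `favored`, stars.
#' @export
compare_dwcs <- function(subject_summaries, occupation = c("D", "DA"),
                         alpha = 0.05) {
  occupation <- match.arg(occupation)
  ss <- subject_summaries[subject_summaries$occupation == occupation, ]
  if (!nrow(ss)) abort_input("no rows for this occupation")
  out <- lapply(intersect(rula_outcomes(), unique(ss$outcome)), function(oc) {
    g <- ss[ss$outcome == oc, ]
    m <- .block_matrix_from_summaries(g, "rel_av_rst")
    if (anyNA(m)) abort_input(paste0("missing (subject, DWC) cells for outcome ", oc))
    fr <- friedman_rank_test(m)
    ci <- conover_iman(m)
    ci$p_adj <- holm_adjust(ci$p_raw)
    means <- colMeans(m)
    sig <- fr$p <= alpha & ci$p_adj <= alpha
    ci$favored <- ifelse(!sig, "none",
                         ifelse(means[ci$first] < means[ci$second],
                                ci$first, ci$second))
    data.frame(outcome = oc, occupation = occupation,
               contrast = paste0(ci$first, "-vs-", ci$second),
               statistic = ci$statistic, p_raw = ci$p_raw, p_adj = ci$p_adj,
               friedman_chi2 = fr$chi2, friedman_p = fr$p,
               favored = ci$favored, stars = signif_stars(ci$p_adj),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Compare occupations within each workplace concept
#'
#' Mann-Whitney U between dentists and assistants on the subject-level
#' rel. av. RST and on the subject-level medians, for every outcome and
#' concept. Holm families are the outcomes within one concept and measure
#' (9 p-values each), mirroring the annotation style of the field's
#' risk tables.
#'
#' @param subject_summaries row-bound [summarize_subject()] outputs.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (dwc, outcome, measure): U, raw and
#'   Holm-adjusted p, `favored` occupation (`"D"`, `"DA"` or `"none"`), stars.
#' @export
compare_occupations <- function(subject_summaries, alpha = 0.05) {
  ss <- subject_summaries
  if (length(unique(ss$occupation)) < 2) {
    abort_input("need both occupations for a comparison")
  }
  out <- list()
  for (dwc in sort(unique(ss$dwc))) {
    for (measure in c("rel_av_rst", "median")) {
      rows <- lapply(intersect(rula_outcomes(), unique(ss$outcome)), function(oc) {
        g <- ss[ss$dwc == dwc & ss$outcome == oc, ]
        a <- g[[measure]][g$occupation == "D"]
        b <- g[[measure]][g$occupation == "DA"]
        mw <- mann_whitney_u(a, b)
        data.frame(dwc = dwc, outcome = oc, measure = measure,
                   U = mw$U, p_raw = mw$p,
                   mean_d = mean(a), mean_da = mean(b),
                   stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      fam$p_adj <- holm_adjust(fam$p_raw)
      fam$favored <- ifelse(fam$p_adj > alpha, "none",
                            ifelse(fam$mean_d < fam$mean_da, "D", "DA"))
      fam$stars <- signif_stars(fam$p_adj)
      out[[length(out) + 1]] <- fam
    }
  }
  res <- do.call(rbind, out)
  res$mean_d <- NULL; res$mean_da <- NULL
  res
}
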