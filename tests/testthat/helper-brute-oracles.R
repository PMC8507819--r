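# Independent brute-force enumerators used as oracles.

brute_friedman_p <- function(x) {
  n <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  stat <- function(rm) {
    Rj <- colSums(rm)
    A <- sum(rm^2)
    d <- A - n * k * (k + 1)^2 / 4
    if (d <= 0) 0 else (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / d
  }
  obs <- stat(r)
  perms <- gtools_perms(k)
  idx <- rep(1, n)
  total <- nrow(perms)^n
  hits <- 0
  for (code in 0:(total - 1)) {
    c0 <- code
    rm <- r
    for (b in 1:n) {
      rm[b, ] <- r[b, perms[c0 %% nrow(perms) + 1, ]]
      c0 <- c0 %/% nrow(perms)
    }
    if (stat(rm) >= obs - 1e-12) hits <- hits + 1
  }
  hits / total
}

gtools_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_perms(k - 1)
  do.call(rbind, lapply(1:k, function(i) {
    cbind(i, matrix((1:k)[-i][sub], nrow(sub)))
  }))
}

brute_mw_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  rk <- rank(c(a, b))
  u_obs <- sum(rk[1:na]) - na * (na + 1) / 2
  us <- apply(utils::combn(N, na), 2, function(idx) {
    sum(rk[idx]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

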