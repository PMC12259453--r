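# Independent brute-force oracles. Each reimplements a statistic from its
# definition (enumeration, direct order statistics, closed form) without
# touching the package's computational path, so agreement is evidence and
# not tautology.

# step-up BH from the definition: sort, p * m / i, cummin from the top, cap
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Kendall tau-b by literal pair enumeration
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1 <- sum(tx * (tx - 1) / 2); u1 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - t1) * (n0 - u1))
}

# Mann-Whitney U by direct pair counting (ties count 1/2)
mw_u_oracle <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
}

# exact two-sided permutation p for the rank-sum by full subset enumeration
mw_exact_p_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  mu <- n1 * length(y) / 2
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - mu)
  subsets <- utils::combn(length(pooled), n1)
  u_all <- apply(subsets, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= obs - 1e-9)
}

# two-sided Fisher p by full hypergeometric enumeration from choose()
fisher_p_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  pk <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- pk[support == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio: maximise the noncentral hypergeometric
# conditional likelihood numerically
fisher_or_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  w <- choose(m, support) * choose(n, k - support)
  loglik <- function(logpsi) {
    lp <- logpsi * support + log(w)
    (logpsi * a) - (max(lp) + log(sum(exp(lp - max(lp)))))
  }
  exp(stats::optimize(loglik, c(-15, 15), maximum = TRUE)$maximum)
}

# type-7 quantile written out from the order statistics
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, n)] - s[lo])
}

winsorize_oracle <- function(x, tail_prob) {
  q_lo <- quantile_oracle(x, tail_prob)
  q_hi <- quantile_oracle(x, 1 - tail_prob)
  pmin(pmax(x, q_lo), q_hi)
}

# Welch's t from the textbook formula with Welch-Satterthwaite df
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
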