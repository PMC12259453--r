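# Rank-based and exact tests used across the pipeline: Mann-Whitney U with
# an exact small-sample permutation distribution, tie-corrected Kendall
# tau-b, Benjamini-Hochberg adjustment, and Fisher's exact 2x2 test.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply the
#' i-th smallest p by m/i, enforce monotonicity from the largest down, cap
#' at 1, restore the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be p-values in [0, 1] without NA.")
  }
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. For small samples
#' (both group sizes <= `exact_max`) the p-value comes from the exact
#' permutation distribution of the rank sum conditional on the observed tie
#' pattern, computed by dynamic programming over subsets; otherwise from the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for which the exact distribution is
#'   enumerated (default 12).
#' @return List with `u` (U statistic of `x`), `p` (two-sided), and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) abort("both samples must be non-empty.")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (max(n1, n2) <= exact_max) {
    # exact permutation distribution of the doubled rank sum (integers even
    # with midranks); counts of subsets of size n1 by sum, via DP
    d <- as.integer(round(2 * r))
    smax <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
    f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
    f[1L, 1L] <- 1
    kmax <- 0L
    for (v in d) {
      kupto <- min(kmax, n1 - 1L)
      for (k in kupto:0) {
        nz <- which(f[k + 1L, ] > 0)
        f[k + 2L, nz + v] <- f[k + 2L, nz + v] + f[k + 1L, nz]
      }
      kmax <- min(kmax + 1L, n1)
    }
    sums <- 0:smax
    cnt <- f[n1 + 1L, ]
    u_all <- sums / 2 - n1 * (n1 + 1) / 2
    dev <- abs(u_all - mu)
    obs <- abs(u - mu)
    p <- sum(cnt[dev >= obs - 1e-9]) / choose(n1 + n2, n1)
    list(u = u, p = min(1, p), method = "exact")
  } else {
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    list(u = u, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
  }
}

# all permutations of 1..n (n small), cached per session
perm_cache <- new.env(parent = emptyenv())
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  p <- if (n == 1L) matrix(1L, 1L, 1L) else {
    sub <- all_perms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      cbind(k, ifelse(sub >= k, sub + 1L, sub))
    }))
  }
  perm_cache[[key]] <- p
  p
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation by direct concordant/discordant pair
#' counting. For `n <= exact_max` without preference, the p-value is exact:
#' the permutation distribution of the concordance statistic S = C - D is
#' enumerated over all orderings of `y` (conditional on ties). For larger
#' `n` the normal approximation with the full tie-corrected variance of S
#' is used.
#'
#' @param x,y Paired numeric vectors (pairs with `NA` dropped), `n >= 3`,
#'   each with at least two distinct values.
#' @param exact_max Largest `n` for which the permutation distribution is
#'   enumerated (default 8).
#' @return List with `tau`, `p` (two-sided), `n`, `method`. When either
#'   input is constant, `tau` and `p` are `NA` and `reason` explains why.
#' @export
kendall_tau_b <- function(x, y, exact_max = 8L) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(tau = NA_real_, p = NA_real_, n = n, method = "none",
                          reason = "fewer than 3 complete pairs"))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(tau = NA_real_, p = NA_real_, n = n, method = "none",
                reason = "constant input"))
  }
  s_stat <- function(xx, yy) {
    dx <- sign(outer(xx, xx, "-")); dy <- sign(outer(yy, yy, "-"))
    sum(dx * dy * upper.tri(dx))
  }
  S <- s_stat(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  t1 <- sum(tx * (tx - 1) / 2); u1 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - t1) * (n0 - u1))
  if (n <= exact_max) {
    perms <- all_perms(n)
    dx <- sign(outer(x, x, "-"))
    ut <- upper.tri(dx)
    svals <- apply(perms, 1L, function(idx) {
      yy <- y[idx]
      dy <- sign(outer(yy, yy, "-"))
      sum(dx * dy * ut)
    })
    p <- mean(abs(svals) >= abs(S) - 1e-9)
    list(tau = tau, p = p, n = n, method = "exact")
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    if (varS <= 0) return(list(tau = tau, p = NA_real_, n = n, method = "normal",
                               reason = "degenerate variance"))
    z <- S / sqrt(varS)
    list(tau = tau, p = min(1, 2 * pnorm(-abs(z))), n = n, method = "normal")
  }
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test on a 2x2 contingency table: the p-value sums the
#' hypergeometric point probabilities not exceeding that of the observed
#' table (with a small relative tolerance), and the odds ratio is the
#' conditional maximum-likelihood estimate.
#'
#' @param tab 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `c(a, b, c, d)` filled by row.
#' @return A one-row tibble: `odds_ratio` (conditional MLE, `Inf` when a
#'   zero cell forces it), `p_value`, `conf_low`, `conf_high`.
#' @export
fisher_2x2 <- function(tab) {
  if (is.numeric(tab) && length(tab) == 4L && is.null(dim(tab))) {
    tab <- matrix(tab, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L))) {
    abort("`tab` must be a 2x2 table.")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`tab` must contain non-negative integers.")
  }
  ft <- stats::fisher.test(tab)
  tibble(
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    conf_low = ft$conf.int[1],
    conf_high = ft$conf.int[2]
  )
}
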