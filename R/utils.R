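# Internal helpers shared across modules.

# Single quantile convention for the whole package (outlier bounds and
# Winsorization must agree): linear interpolation between order statistics,
# i.e. stats::quantile type 7.
quantile7 <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = FALSE))
}

assert_fraction <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must be a fraction in [%s, %s].", name,
                  if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)"))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  if (x > .Machine$integer.max) {
    abort(sprintf("`%s` must be below 2^31.", name))
  }
  invisible(as.integer(x))
}

# deterministic integer -> synthetic CDR3 strings -----------------------------

aa16 <- c("G", "A", "S", "T", "N", "D", "E", "Q",
          "K", "R", "H", "L", "I", "V", "F", "W")
codon16 <- c("GGC", "GCC", "AGC", "ACC", "AAC", "GAC", "GAG", "CAG",
             "AAG", "CGG", "CAC", "CTG", "ATC", "GTG", "TTC", "TGG")

cdr3_flanks_aa <- c("EQYF", "TQYF", "QPQHF")
cdr3_flanks_nt <- c("GAGCAGTACTTC", "ACCCAGTACTTC", "CAGCCCCAGCACTTC")
cdr3_prefix_aa <- "CASS"
cdr3_prefix_nt <- "TGTGCCAGCAGC"

# Encode integer ids (1 <= id < 16^6) as unique, valid-looking CDR3 beta
# amino-acid sequences plus a consistent naive nucleotide rearrangement.
# The body is the base-16 expansion of the id mapped onto 16 amino acids, so
# distinct ids can never collide; the C-terminal flank varies with id %% 3.
encode_cdr3 <- function(ids) {
  ids <- as.integer(ids)
  if (any(ids < 1L) || any(ids >= 16^6)) {
    abort("internal: cdr3 ids must lie in [1, 16^6).")
  }
  digit <- function(k) (ids %/% as.integer(16^(6 - k))) %% 16L + 1L
  cols_aa <- lapply(1:6, function(k) aa16[digit(k)])
  cols_nt <- lapply(1:6, function(k) codon16[digit(k)])
  fl <- ids %% 3L + 1L
  aa <- do.call(paste0, c(list(cdr3_prefix_aa), cols_aa, list(cdr3_flanks_aa[fl])))
  nt <- do.call(paste0, c(list(cdr3_prefix_nt), cols_nt, list(cdr3_flanks_nt[fl])))
  list(aa = aa, nt = nt)
}

# Welch two-sample t-test as a tidy one-row tibble; NA row when either side
# has fewer than 2 values or both are constant.
welch_row <- function(x, y, labels = c("x", "y")) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  out <- tibble(
    n_x = length(x), n_y = length(y),
    mean_x = if (length(x)) mean(x) else NA_real_,
    mean_y = if (length(y)) mean(y) else NA_real_,
    statistic = NA_real_, df = NA_real_, p_value = NA_real_
  )
  if (length(x) >= 2L && length(y) >= 2L && (sd(x) > 0 || sd(y) > 0)) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    out$statistic <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p_value <- tt$p.value
  }
  names(out)[1:4] <- c(paste0("n_", labels), paste0("mean_", labels))
  out
}
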