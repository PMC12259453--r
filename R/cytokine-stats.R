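# Cytokine preprocessing and group comparison: IQR outlier screening,
# log2(x + 1), Winsorization, row Z-scoring, and per-analyte two-group tests
# with Benjamini-Hochberg control. The preprocessing order is fixed:
# outlier removal -> log2(x + 1) -> Winsorization -> correlation.

#' log2(x + 1) transform
#'
#' Variance-stabilising transform applied to raw concentrations before
#' correlation analysis; the pseudocount of 1 accommodates true zeros.
#' `NA` (not detected) cells pass through unchanged.
#'
#' @param x Numeric vector or matrix of non-negative values.
#' @return Transformed values, same shape as `x`.
#' @export
log2p1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("log2p1() requires non-negative values.")
  log2(x + 1)
}

#' Winsorize a numeric vector
#'
#' Values below the `tail_prob` quantile are set to that quantile, values
#' above the `1 - tail_prob` quantile to that quantile (type-7 quantiles,
#' the same convention as [detect_outliers()]). `NA` cells are ignored and
#' preserved.
#'
#' @param x Numeric vector with at least two finite values.
#' @param tail_prob Tail mass clamped on each side, in `[0, 0.5)`.
#'   Default 0.125, i.e. clamping at the 12.5% and 87.5% quantiles.
#' @return Winsorized vector of the same length.
#' @export
winsorize <- function(x, tail_prob = 0.125) {
  if (!is.numeric(tail_prob) || length(tail_prob) != 1L ||
      is.na(tail_prob) || tail_prob < 0 || tail_prob >= 0.5) {
    abort("`tail_prob` must lie in [0, 0.5).")
  }
  ok <- is.finite(x)
  if (sum(ok) < 2L) abort("winsorize() needs at least two finite values.")
  q <- quantile7(x[ok], c(tail_prob, 1 - tail_prob))
  x[ok] <- pmin(pmax(x[ok], q[1]), q[2])
  x
}

#' Row-wise Z-scoring of a matrix
#'
#' Centres and scales each row to mean 0 and sample standard deviation 1
#' (n - 1 denominator), excluding `NA` (not detected) cells, which remain
#' `NA`. Zero-variance rows are set to all zeros with a warning.
#'
#' @param mat Numeric matrix; rows are the units to scale (e.g. analytes
#'   across samples). Each row needs at least two non-`NA` values.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  if (!is.matrix(mat)) abort("`mat` must be a matrix.")
  out <- mat
  flat <- character()
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      abort(sprintf("row %d has fewer than 2 detected values.", i))
    }
    s <- sd(v[ok])
    if (s == 0) {
      out[i, ok] <- 0
      flat <- c(flat, rownames(mat)[i] %||% as.character(i))
    } else {
      out[i, ok] <- (v[ok] - mean(v[ok])) / s
    }
  }
  if (length(flat)) {
    warn(paste0("zero-variance rows set to 0: ", paste(flat, collapse = ", ")))
  }
  out
}

#' Flag outlying cytokine measurements by the IQR rule
#'
#' Within each (analyte, group), values below `Q1 - k * IQR` or above
#' `Q3 + k * IQR` (strict inequalities; type-7 quartiles) are flagged.
#' A sample is proposed for removal when it is flagged in at least
#' `sample_flag_fraction` of the analytes evaluated for it.
#'
#' @param panel A [cytokine_panel].
#' @param groups Named character vector mapping sample id to group, or a
#'   data frame with columns `sample_id` and `group`.
#' @param k IQR multiplier (default 2).
#' @param sample_flag_fraction Fraction of flagged analytes at or above which
#'   a sample is listed in `removed_samples` (default 0.25).
#' @param min_detected Minimum detected values per (analyte, group) required
#'   to compute quartiles; analytes below it are skipped with a warning.
#' @return An `outlier_report`: list with `stats` (per analyte and group:
#'   `q1`, `q3`, `iqr`, bounds, flag count), `flags` (one row per flagged
#'   cell), `samples` (per-sample flag fractions), `removed_samples`, and
#'   `skipped` (analyte/group pairs without enough data).
#' @export
detect_outliers <- function(panel, groups, k = 2, sample_flag_fraction = 0.25,
                            min_detected = 4L) {
  stopifnot(inherits(panel, "cytokine_panel"))
  groups <- group_lookup(groups, rownames(panel$values))
  if (any(table(groups) == 0L)) abort("empty group in `groups`.")
  v <- panel$values
  stats_rows <- list(); flag_rows <- list(); skipped <- list()
  for (g in unique(groups)) {
    rows <- names(groups)[groups == g]
    for (a in colnames(v)) {
      x <- v[rows, a]
      ok <- !is.na(x)
      if (sum(ok) < min_detected) {
        skipped[[length(skipped) + 1L]] <- tibble(analyte = a, group = g, n_detected = sum(ok))
        next
      }
      q <- quantile7(x[ok], c(0.25, 0.75))
      iqr <- q[2] - q[1]
      lo <- q[1] - k * iqr
      hi <- q[2] + k * iqr
      bad <- ok & (x < lo | x > hi)
      stats_rows[[length(stats_rows) + 1L]] <- tibble(
        analyte = a, group = g, n_detected = sum(ok),
        q1 = q[1], q3 = q[2], iqr = iqr, lower = lo, upper = hi,
        n_flagged = sum(bad)
      )
      if (any(bad)) {
        flag_rows[[length(flag_rows) + 1L]] <- tibble(
          sample_id = rows[bad], analyte = a, group = g,
          value = x[bad], side = ifelse(x[bad] < lo, "low", "high")
        )
      }
    }
  }
  if (length(skipped)) {
    sk <- dplyr::bind_rows(skipped)
    warn(sprintf("%d (analyte, group) pairs skipped: fewer than %d detected values.",
                 nrow(sk), min_detected))
  } else {
    sk <- tibble(analyte = character(), group = character(), n_detected = integer())
  }
  stats <- dplyr::bind_rows(stats_rows)
  flags <- if (length(flag_rows)) dplyr::bind_rows(flag_rows) else
    tibble(sample_id = character(), analyte = character(), group = character(),
           value = double(), side = character())
  # per-sample flag fraction over the analytes actually evaluated for its group
  evaluated <- stats |>
    dplyr::count(.data$group, name = "n_analytes")
  samples <- tibble(sample_id = names(groups), group = unname(groups)) |>
    dplyr::left_join(dplyr::count(flags, .data$sample_id, name = "n_flagged"),
                     by = "sample_id") |>
    dplyr::left_join(evaluated, by = "group") |>
    dplyr::mutate(
      n_flagged = dplyr::coalesce(.data$n_flagged, 0L),
      n_analytes = dplyr::coalesce(.data$n_analytes, 0L),
      flag_fraction = ifelse(.data$n_analytes > 0, .data$n_flagged / .data$n_analytes, 0)
    )
  removed <- samples$sample_id[samples$flag_fraction >= sample_flag_fraction &
                                 samples$n_analytes > 0]
  structure(
    list(stats = stats, flags = flags, samples = samples,
         removed_samples = removed, skipped = sk,
         k = k, sample_flag_fraction = sample_flag_fraction),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d flagged cells; %d sample(s) proposed for removal",
              nrow(x$flags), length(x$removed_samples)))
  if (length(x$removed_samples)) cat(":", paste(x$removed_samples, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.outlier_report <- function(x, ...) x$flags

#' @exportS3Method generics::glance
glance.outlier_report <- function(x, ...) {
  tibble(n_flagged_cells = nrow(x$flags),
         n_removed_samples = length(x$removed_samples),
         n_skipped = nrow(x$skipped))
}

#' Preprocess a cytokine matrix for correlation analysis
#'
#' Applies the fixed preprocessing chain to the samples of one group within
#' one compartment: (1) IQR outlier screening with sample-level removal,
#' (2) `log2(x + 1)`, (3) per-analyte Winsorization. Not-detected cells stay
#' `NA` throughout.
#'
#' @param panel A [cytokine_panel].
#' @param sample_ids Samples forming the matrix (one group, one compartment).
#' @inheritParams detect_outliers
#' @inheritParams winsorize
#' @return List with `matrix` (processed samples x analytes matrix) and
#'   `outliers` (the [detect_outliers()] report used for removal).
#' @export
preprocess_cytokines <- function(panel, sample_ids = rownames(panel$values),
                                 k = 2, sample_flag_fraction = 0.25,
                                 tail_prob = 0.125, min_detected = 4L) {
  sub <- panel_subset(panel, sample_ids)
  groups <- setNames(rep("all", length(sample_ids)), sample_ids)
  rep_out <- detect_outliers(sub, groups, k = k,
                             sample_flag_fraction = sample_flag_fraction,
                             min_detected = min_detected)
  keep <- setdiff(sample_ids, rep_out$removed_samples)
  m <- log2p1(sub$values[keep, , drop = FALSE])
  for (j in seq_len(ncol(m))) {
    if (sum(is.finite(m[, j])) >= 2L) m[, j] <- winsorize(m[, j], tail_prob)
  }
  list(matrix = m, outliers = rep_out)
}

#' Compare cytokine levels between two groups
#'
#' Per-analyte two-group comparison on the raw concentration scale with
#' Benjamini-Hochberg adjustment across all analytes tested. Fold change is
#' the ratio of raw group means (the ratio of medians is also reported).
#'
#' @param panel A [cytokine_panel].
#' @param groups Named character vector (or `sample_id`/`group` data frame)
#'   assigning each sample to one of exactly two groups.
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @param alpha Significance level applied to BH-adjusted p-values.
#' @param reference Group used as the fold-change denominator; default the
#'   second group level (alphabetical).
#' @param exclude_samples Samples dropped before testing (e.g. outliers).
#' @return A tibble with one row per tested analyte: group means, `fold_change`
#'   (mean ratio, numerator = non-reference group), `median_ratio`,
#'   `statistic`, `raw_p`, `adjusted_p`, `significant`. Skipped analytes
#'   (fewer than 2 detected values in either group) are recorded in the
#'   `"skipped"` attribute.
#' @export
compare_cytokine_groups <- function(panel, groups,
                                    test = c("mann_whitney", "welch_t"),
                                    alpha = 0.05, reference = NULL,
                                    exclude_samples = character()) {
  test <- match.arg(test)
  stopifnot(inherits(panel, "cytokine_panel"))
  groups <- group_lookup(groups, rownames(panel$values))
  groups <- groups[setdiff(names(groups), exclude_samples)]
  lv <- sort(unique(groups))
  if (length(lv) != 2L) abort("`groups` must define exactly two groups.")
  reference <- reference %||% lv[2]
  if (!reference %in% lv) abort("`reference` is not one of the groups.")
  numer <- setdiff(lv, reference)
  v <- panel$values
  rows <- list(); skipped <- character()
  for (a in colnames(v)) {
    x <- v[names(groups)[groups == numer], a]; x <- x[!is.na(x)]
    y <- v[names(groups)[groups == reference], a]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) { skipped <- c(skipped, a); next }
    if (test == "mann_whitney") {
      ht <- mann_whitney_u(x, y)
      stat <- ht$u; pv <- ht$p
    } else {
      tt <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(tt$statistic); pv <- tt$p.value
    }
    rows[[length(rows) + 1L]] <- tibble(
      analyte = a, n_1 = length(x), n_2 = length(y),
      mean_1 = mean(x), mean_2 = mean(y),
      fold_change = mean(x) / mean(y),
      median_ratio = median(x) / median(y),
      statistic = stat, raw_p = pv
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out$adjusted_p <- bh_adjust(out$raw_p)
    out$significant <- out$adjusted_p < alpha
  }
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(numerator = numer, reference = reference)
  attr(out, "test") <- test
  out
}

group_lookup <- function(groups, sample_ids) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample_id)
  }
  if (is.null(names(groups))) abort("`groups` must be named by sample id.")
  groups <- groups[intersect(sample_ids, names(groups))]
  if (!length(groups)) abort("no overlap between `groups` and panel samples.")
  groups
}

#' Hierarchical row order for heatmap reproduction
#'
#' Euclidean-distance, complete-linkage ordering of matrix rows (e.g.
#' Z-scored analytes), exported so a heatmap's row arrangement can be
#' reproduced without any plotting here. Rows with missing cells use
#' pairwise-complete distances.
#'
#' @param mat Numeric matrix (rows to order).
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return Integer vector: the leaf order of the dendrogram.
#' @export
cluster_order <- function(mat, method = "complete") {
  if (!is.matrix(mat) || nrow(mat) < 2L) abort("`mat` must have at least 2 rows.")
  d <- stats::dist(mat)
  if (anyNA(d)) {
    # pairwise-complete Euclidean distances, scaled to full dimension
    n <- nrow(mat)
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
        if (!any(ok)) abort(sprintf("rows %d and %d share no observed cells.", i, j))
        dm[i, j] <- dm[j, i] <-
          sqrt(sum((mat[i, ok] - mat[j, ok])^2) * ncol(mat) / sum(ok))
      }
    }
    d <- stats::as.dist(dm)
  }
  stats::hclust(d, method = method)$order
}
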