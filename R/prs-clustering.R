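# Potentially relevant sequences (PRS): selection from MS CSF, rank-matrix
# construction over MS and healthy-reference samples, k-means (k = 2) with
# post-hoc MS-cluster labelling, PCA projection, and the cluster occurrence
# test.

#' Identify potentially relevant sequences (PRS) from MS CSF
#'
#' A CDR3.aa sequence is a PRS if it (1) ranks among the top `top_n`
#' sequences by clone count in the CSF of at least one MS patient and has a
#' clone count of at least `min_count` there (ties at the boundary rank are
#' all included), or (2) occurs in the CSF of at least `min_patients`
#' different MS patients.
#'
#' @param ledger A [clone_ledger()] covering the MS CSF samples.
#' @param top_n Per-patient top rank cut (default 10).
#' @param min_count Minimum clone count for criterion 1 (default 2).
#' @param min_patients Minimum distinct MS patients for criterion 2
#'   (default 2).
#' @return Tibble with `cdr3_aa`, criterion flags `top10_csf` and
#'   `multi_patient_csf`, `n_patients` (distinct MS CSF patients), and
#'   `patients` (comma-separated source patients). The numbers of
#'   criterion-1 hits, criterion-2 hits and the union are stored in the
#'   `"counts"` attribute.
#' @export
identify_prs <- function(ledger, top_n = 10L, min_count = 2L, min_patients = 2L) {
  stopifnot(inherits(ledger, "clone_ledger"))
  csf <- ledger$clones |>
    dplyr::filter(.data$group == "MS", .data$compartment == "CSF")
  empty <- tibble(cdr3_aa = character(), top10_csf = logical(),
                  multi_patient_csf = logical(), n_patients = integer(),
                  patients = character())
  if (!nrow(csf)) {
    attr(empty, "counts") <- c(criterion1 = 0L, criterion2 = 0L, union = 0L)
    return(empty)
  }
  crit1 <- csf |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(cut = sort(.data$templates, decreasing = TRUE)[
      pmin(top_n, dplyr::n())]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$templates >= .data$cut, .data$templates >= min_count) |>
    dplyr::distinct(.data$cdr3_aa) |>
    dplyr::pull(.data$cdr3_aa)
  occupancy <- csf |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(n_patients = dplyr::n_distinct(.data$patient_id),
                     patients = paste(sort(unique(.data$patient_id)), collapse = ","),
                     .groups = "drop")
  crit2 <- occupancy$cdr3_aa[occupancy$n_patients >= min_patients]
  seqs <- sort(union(crit1, crit2))
  out <- tibble(cdr3_aa = seqs) |>
    dplyr::left_join(occupancy, by = "cdr3_aa") |>
    dplyr::mutate(top10_csf = .data$cdr3_aa %in% crit1,
                  multi_patient_csf = .data$cdr3_aa %in% crit2) |>
    dplyr::select("cdr3_aa", "top10_csf", "multi_patient_csf",
                  "n_patients", "patients")
  attr(out, "counts") <- c(criterion1 = length(crit1), criterion2 = length(crit2),
                           union = length(seqs))
  out
}

#' Build the PRS rank matrix
#'
#' For each sample, the clone counts of all PRS are ranked within that
#' sample: rank 1 is the largest count, ties get average ranks, and
#' sequences absent from the sample share the tied bottom rank (counts of
#' zero). One row per PRS, one column (dimension) per sample.
#'
#' @param prs PRS set: character vector of sequences or an
#'   [identify_prs()] result.
#' @param ledger A [clone_ledger()] covering the rank-matrix samples.
#' @param sample_ids Samples forming the columns. Default: all blood
#'   samples of the `HEALTHY_REF` and `MS` groups present in the ledger
#'   (the healthy-reference cohort plus the MS patients with blood
#'   available).
#' @return Numeric matrix of ranks (rows = PRS, columns = samples) with the
#'   raw count matrix in the `"counts"` attribute.
#' @export
build_rank_matrix <- function(prs, ledger, sample_ids = NULL) {
  stopifnot(inherits(ledger, "clone_ledger"))
  seqs <- if (is.data.frame(prs)) prs$cdr3_aa else prs
  if (!length(seqs)) abort("the PRS set is empty.")
  sample_ids <- sample_ids %||% (ledger$samples |>
    dplyr::filter(.data$compartment == "blood",
                  .data$group %in% c("HEALTHY_REF", "MS")) |>
    dplyr::pull(.data$sample_id))
  if (!length(sample_ids)) abort("no samples for the rank matrix.")
  counts <- matrix(0, nrow = length(seqs), ncol = length(sample_ids),
                   dimnames = list(seqs, sample_ids))
  hits <- ledger$clones |>
    dplyr::filter(.data$cdr3_aa %in% seqs, .data$sample_id %in% sample_ids)
  if (nrow(hits)) {
    counts[cbind(match(hits$cdr3_aa, seqs), match(hits$sample_id, sample_ids))] <-
      hits$templates
  }
  ranks <- apply(counts, 2L, function(v) rank(-v, ties.method = "average"))
  ranks <- matrix(ranks, nrow = length(seqs), dimnames = dimnames(counts))
  attr(ranks, "counts") <- counts
  ranks
}

#' k-means clustering of PRS rank profiles (k = 2)
#'
#' Euclidean k-means with two centers and `n_init` seeded restarts,
#' deterministic given `seed`. The cluster whose sequences occur in a
#' higher mean fraction of MS samples is labelled `ms_associated`, the
#' other `general`.
#'
#' @param rank_matrix A [build_rank_matrix()] result.
#' @param ms_samples Column names belonging to MS samples (used for the
#'   post-hoc labelling and occurrence summaries); the remaining columns
#'   are treated as the healthy reference.
#' @param seed Integer RNG seed.
#' @param n_init Number of random restarts (default 25).
#' @return A `prs_clusters` object: list with `assignment` (sequence,
#'   cluster, label), `occurrence` (per-sequence percent of MS and healthy
#'   samples containing it), `cluster_means`, `within_ss`, and the inputs
#'   needed by [cluster_occurrence_test()].
#' @export
kmeans_two <- function(rank_matrix, ms_samples, seed = 1L, n_init = 25L) {
  if (nrow(rank_matrix) < 2L) abort("need at least 2 PRS rows to cluster.")
  if (!all(ms_samples %in% colnames(rank_matrix))) {
    abort("`ms_samples` must be columns of the rank matrix.")
  }
  if (all(apply(rank_matrix, 2L, function(v) length(unique(v)) == 1L))) {
    abort("all rank profiles are identical; clustering is degenerate - inspect the PRS counts.")
  }
  counts <- attr(rank_matrix, "counts")
  if (is.null(counts)) abort("`rank_matrix` must carry its \"counts\" attribute.")
  healthy_samples <- setdiff(colnames(rank_matrix), ms_samples)
  set.seed(seed)
  if (nrow(rank_matrix) == 2L) {
    # k equals the number of profiles: the partition is the identity
    km <- list(cluster = c(1L, 2L), centers = rank_matrix, tot.withinss = 0)
  } else {
    km <- stats::kmeans(rank_matrix, centers = 2L, nstart = n_init)
  }
  occ <- tibble(
    cdr3_aa = rownames(rank_matrix),
    occ_ms = unname(100 * rowMeans(counts[, ms_samples, drop = FALSE] > 0)),
    occ_healthy = if (length(healthy_samples))
      unname(100 * rowMeans(counts[, healthy_samples, drop = FALSE] > 0))
    else NA_real_
  )
  mean_occ <- vapply(1:2, function(k) mean(occ$occ_ms[km$cluster == k]), 0)
  ms_cluster <- which.max(mean_occ)
  assignment <- tibble(
    cdr3_aa = rownames(rank_matrix),
    cluster = as.integer(km$cluster),
    label = ifelse(km$cluster == ms_cluster, "ms_associated", "general")
  )
  structure(
    list(assignment = assignment, occurrence = occ,
         cluster_means = tibble(cluster = 1:2, mean_occ_ms = mean_occ,
                                label = ifelse(1:2 == ms_cluster,
                                               "ms_associated", "general")),
         within_ss = km$tot.withinss, centers = km$centers,
         n_ms_samples = length(ms_samples),
         n_healthy_samples = length(healthy_samples)),
    class = "prs_clusters"
  )
}

#' @export
print.prs_clusters <- function(x, ...) {
  tab <- table(x$assignment$label)
  cat(sprintf("<prs_clusters> %s\n",
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prs_clusters <- function(x, ...) {
  dplyr::left_join(x$assignment, x$occurrence, by = "cdr3_aa")
}

#' PCA projection of a rank matrix
#'
#' Centred principal-component projection onto the first two components for
#' cluster visualisation. Component signs are fixed by making each
#' component's largest-magnitude loading positive, so the projection is
#' fully deterministic.
#'
#' @param mat Numeric matrix (rows = PRS).
#' @return List with `coords` (cdr3_aa, pc1, pc2) and `var_explained`
#'   (fraction of variance per retained component).
#' @export
pca_project <- function(mat) {
  if (nrow(mat) < 2L) abort("need at least 2 rows for PCA.")
  if (all(apply(mat, 2L, stats::var) == 0)) abort("zero-variance matrix.")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- tibble(
    cdr3_aa = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    pc1 = pc$x[, 1],
    pc2 = if (k >= 2L) pc$x[, 2] else 0
  )
  list(coords = coords, var_explained = ev[seq_len(k)])
}

#' Occurrence test per PRS cluster
#'
#' The occurrence of a sequence in a group is the percentage of that
#' group's samples containing it (count > 0). Within each cluster, the MS
#' and healthy occurrence vectors (one value per sequence) are compared
#' with Welch's t-test. Clusters with fewer than two sequences are skipped
#' and recorded.
#'
#' @param clusters A [kmeans_two()] result.
#' @return Tibble with one row per cluster label: sequence count, mean
#'   occurrences, Welch statistic, df and p-value (`NA` when skipped).
#' @export
cluster_occurrence_test <- function(clusters) {
  stopifnot(inherits(clusters, "prs_clusters"))
  dat <- dplyr::left_join(clusters$assignment, clusters$occurrence, by = "cdr3_aa")
  rows <- lapply(sort(unique(dat$label)), function(lb) {
    sub <- dat[dat$label == lb, ]
    dplyr::bind_cols(
      tibble(label = lb, n_sequences = nrow(sub)),
      welch_row(sub$occ_ms, sub$occ_healthy, labels = c("occ_ms", "occ_healthy"))
    )
  })
  dplyr::bind_rows(rows)
}
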