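# Repertoire statistics: clone sharing and recovery between paired CSF and
# blood, Simpson clonality, per-sample summaries with Welch tests, and TRBV
# gene-usage comparison.

#' Clone sharing between paired CSF and blood
#'
#' For every patient with both compartments, counts the distinct CDR3.aa
#' clones of each compartment and their intersection, and reports both
#' recovery directions: the percentage of blood clones also found in CSF
#' and the percentage of CSF clones also found in blood (same intersection,
#' different denominators). Group means (MS vs CTRL) are compared by Welch's
#' t-test for each direction. Patients missing a compartment are excluded
#' and recorded.
#'
#' @param ledger A [clone_ledger()].
#' @return A `sharing_summary`: list with `patients` (per-patient counts and
#'   percentages), `tests` (Welch test per direction), `excluded` (patients
#'   without a pair).
#' @export
sharing_summary <- function(ledger) {
  stopifnot(inherits(ledger, "clone_ledger"))
  wide <- ledger$clones |>
    dplyr::distinct(.data$patient_id, .data$group, .data$compartment, .data$cdr3_aa)
  comp_per_patient <- wide |>
    dplyr::distinct(.data$patient_id, .data$group, .data$compartment) |>
    dplyr::count(.data$patient_id, .data$group, name = "n_compartments")
  excluded <- comp_per_patient |>
    dplyr::filter(.data$n_compartments < 2L)
  paired <- comp_per_patient |>
    dplyr::filter(.data$n_compartments == 2L) |>
    dplyr::pull(.data$patient_id)
  pat_rows <- lapply(paired, function(p) {
    pw <- wide[wide$patient_id == p, ]
    blood <- pw$cdr3_aa[pw$compartment == "blood"]
    csf <- pw$cdr3_aa[pw$compartment == "CSF"]
    shared <- length(intersect(blood, csf))
    tibble(
      patient_id = p, group = pw$group[1],
      n_blood = length(blood), n_csf = length(csf), n_shared = shared,
      pct_shared_of_blood = 100 * shared / length(blood),
      pct_shared_of_csf = 100 * shared / length(csf)
    )
  })
  patients <- dplyr::bind_rows(pat_rows)
  tests <- NULL
  if (nrow(patients)) {
    ms <- patients[patients$group == "MS", ]
    ct <- patients[patients$group == "CTRL", ]
    tests <- dplyr::bind_rows(
      dplyr::bind_cols(tibble(direction = "pct_shared_of_blood"),
                       welch_row(ms$pct_shared_of_blood, ct$pct_shared_of_blood,
                                 labels = c("ms", "ctrl"))),
      dplyr::bind_cols(tibble(direction = "pct_shared_of_csf"),
                       welch_row(ms$pct_shared_of_csf, ct$pct_shared_of_csf,
                                 labels = c("ms", "ctrl")))
    )
  }
  structure(list(patients = patients, tests = tests, excluded = excluded),
            class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d paired patients (%d excluded)\n",
              nrow(x$patients), nrow(x$excluded)))
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sharing_summary <- function(x, ...) x$patients

#' @exportS3Method generics::glance
glance.sharing_summary <- function(x, ...) x$tests

#' Simpson clonality
#'
#' The square root of the Simpson index over productive clone frequencies,
#' `sqrt(sum(p_i^2))` (the immunoSEQ-analyzer convention): 1 for a
#' monoclonal sample, `1/sqrt(N)` for a uniform repertoire of N clones,
#' approaching 0 with increasing evenness. The normalized-entropy
#' alternative `1 - H/ln(R)` is available via `definition`.
#'
#' @param counts Positive clone counts (one sample).
#' @param definition `"simpson"` (default) or `"normalized_entropy"`.
#' @return Clonality in `(0, 1]`.
#' @export
simpson_clonality <- function(counts, definition = c("simpson", "normalized_entropy")) {
  definition <- match.arg(definition)
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts)) abort("`counts` must contain at least one positive count.")
  p <- counts / sum(counts)
  if (definition == "simpson") {
    sqrt(sum(p^2))
  } else {
    if (length(p) == 1L) return(1)
    1 - (-sum(p * log(p))) / log(length(p))
  }
}

#' Per-sample repertoire statistics with group tests
#'
#' Computes, per sample: total templates (productive plus non-productive,
#' the "total T cells" readout), productive templates, productive
#' rearrangements, maximum clone frequency (largest CDR3.aa-aggregated
#' productive clone, percent of productive templates) and Simpson
#' clonality. Each statistic is compared between MS and CTRL with Welch's
#' t-test, separately per compartment.
#'
#' @param ledger A [clone_ledger()].
#' @return List with `samples` (per-sample statistics) and `tests`
#'   (per statistic, per compartment Welch comparison).
#' @export
sample_statistics <- function(ledger) {
  stopifnot(inherits(ledger, "clone_ledger"))
  per_sample <- ledger$clones |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      max_clone_templates = max(.data$templates),
      clonality = simpson_clonality(.data$templates),
      .groups = "drop"
    )
  samples <- ledger$samples |>
    dplyr::left_join(per_sample, by = "sample_id") |>
    dplyr::mutate(
      max_clone_freq_pct = 100 * .data$max_clone_templates /
        pmax(.data$productive_templates, 1L)
    ) |>
    dplyr::select(-"max_clone_templates")
  stats_cols <- c("total_templates", "productive_templates",
                  "productive_rearrangements", "max_clone_freq_pct", "clonality")
  test_rows <- list()
  for (comp in unique(samples$compartment)) {
    sub <- samples[samples$compartment == comp, ]
    for (st in stats_cols) {
      x <- sub[[st]][sub$group == "MS"]
      y <- sub[[st]][sub$group == "CTRL"]
      if (!length(x) || !length(y)) next
      test_rows[[length(test_rows) + 1L]] <- dplyr::bind_cols(
        tibble(compartment = comp, statistic_name = st),
        welch_row(x, y, labels = c("ms", "ctrl"))
      )
    }
  }
  list(samples = samples, tests = dplyr::bind_rows(test_rows))
}

#' TRBV gene usage
#'
#' Per-sample relative proportion of productive templates attributed to each
#' TRBV gene segment (proportions sum to 1 within a sample), per-gene MS vs
#' CTRL Mann-Whitney comparison with BH adjustment across genes (within each
#' compartment), and a variability ranking of genes by cross-sample variance
#' of their proportions.
#'
#' @param rearrangements Long rearrangement tibble (see [clone_ledger()]).
#' @param productive_only Use productive rows only (default `TRUE`).
#' @param alpha Significance level on BH-adjusted p-values.
#' @return List with `proportions` (sample x gene, long), `tests` (per gene
#'   and compartment) and `variability` (genes ranked by variance).
#' @export
trbv_usage <- function(rearrangements, productive_only = TRUE, alpha = 0.05) {
  rr <- if (productive_only) dplyr::filter(rearrangements, .data$productive) else rearrangements
  totals <- rr |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$templates), .groups = "drop")
  props <- rr |>
    dplyr::group_by(.data$sample_id, .data$patient_id, .data$compartment,
                    .data$group, .data$v_gene) |>
    dplyr::summarise(templates = sum(.data$templates), .groups = "drop") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(proportion = .data$templates / .data$total)
  test_rows <- list()
  for (comp in unique(props$compartment)) {
    sub <- props[props$compartment == comp, ]
    samp <- dplyr::distinct(sub, .data$sample_id, .data$group)
    if (dplyr::n_distinct(samp$group[samp$group %in% c("MS", "CTRL")]) < 2L) next
    for (g in sort(unique(sub$v_gene))) {
      # absent gene in a sample means proportion 0
      gx <- sub[sub$v_gene == g, c("sample_id", "proportion")]
      full <- samp |>
        dplyr::left_join(gx, by = "sample_id") |>
        dplyr::mutate(proportion = dplyr::coalesce(.data$proportion, 0))
      x <- full$proportion[full$group == "MS"]
      y <- full$proportion[full$group == "CTRL"]
      if (length(x) < 2L || length(y) < 2L) next
      mw <- mann_whitney_u(x, y)
      test_rows[[length(test_rows) + 1L]] <- tibble(
        compartment = comp, v_gene = g,
        mean_ms = mean(x), mean_ctrl = mean(y),
        u = mw$u, raw_p = mw$p
      )
    }
  }
  tests <- dplyr::bind_rows(test_rows)
  if (nrow(tests)) {
    tests <- tests |>
      dplyr::group_by(.data$compartment) |>
      dplyr::mutate(adjusted_p = bh_adjust(.data$raw_p)) |>
      dplyr::ungroup() |>
      dplyr::mutate(significant = .data$adjusted_p < alpha)
  }
  variability <- props |>
    dplyr::group_by(.data$compartment, .data$v_gene) |>
    dplyr::summarise(variance = stats::var(.data$proportion), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$compartment, dplyr::desc(.data$variance))
  list(proportions = props, tests = tests, variability = variability)
}
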