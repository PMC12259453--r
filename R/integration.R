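# TCR-cytokine integration: public prefilter, MS-predominant selection,
# Kendall tau-b association of blood clone proportions with blood cytokine
# levels, BH control and tabulation by analyte and functional category.

#' Select public CDR3.aa sequences
#'
#' Public sequences are those detected (count > 0) in at least
#' `min_samples` distinct samples of the analysis set.
#'
#' @param ledger A [clone_ledger()].
#' @param min_samples Minimum distinct samples (default 2).
#' @param sample_ids Samples defining the analysis set; default all samples
#'   in the ledger.
#' @return Tibble with `cdr3_aa` and `n_samples`.
#' @export
select_public <- function(ledger, min_samples = 2L, sample_ids = NULL) {
  stopifnot(inherits(ledger, "clone_ledger"))
  cl <- ledger$clones
  if (!is.null(sample_ids)) cl <- cl[cl$sample_id %in% sample_ids, ]
  dt <- data.table::as.data.table(cl[, c("cdr3_aa", "sample_id")])
  occ <- tibble::as_tibble(dt[, list(n_samples = data.table::uniqueN(sample_id)),
                              by = "cdr3_aa"])
  dplyr::arrange(occ[occ$n_samples >= min_samples, ], .data$cdr3_aa)
}

# per-patient clone proportions in one compartment: summed CDR3.aa
# productive templates over the sample's productive template total;
# absent sequences contribute proportion 0
clone_proportions <- function(ledger, sequences, compartment = "blood",
                              groups = c("MS", "CTRL")) {
  samp <- ledger$samples |>
    dplyr::filter(.data$compartment == !!compartment, .data$group %in% groups)
  hits <- ledger$clones |>
    dplyr::filter(.data$cdr3_aa %in% sequences,
                  .data$sample_id %in% samp$sample_id) |>
    dplyr::select("cdr3_aa", "sample_id", "templates")
  tidyr::expand_grid(cdr3_aa = sequences, sample_id = samp$sample_id) |>
    dplyr::left_join(hits, by = c("cdr3_aa", "sample_id")) |>
    dplyr::left_join(samp[, c("sample_id", "patient_id", "group",
                              "productive_templates")], by = "sample_id") |>
    dplyr::mutate(templates = dplyr::coalesce(.data$templates, 0L),
                  proportion = .data$templates / .data$productive_templates)
}

#' Select MS-predominant sequences
#'
#' From the public sequences, selects those that are either (rule A)
#' present in at least `min_ms` MS patients' blood and in no control, or
#' (rule B) present in both groups with a mean blood clone proportion at
#' least `enrichment_fold` times higher in MS. Rule A takes precedence when
#' both hold. The log2 enrichment of mean proportions uses a pseudocount
#' (default: half the smallest nonzero proportion observed cohort-wide) so
#' control-absent sequences still get a finite fold change.
#'
#' @param ledger A [clone_ledger()] covering MS and CTRL blood.
#' @param public Public sequence set (tibble from [select_public()] or a
#'   character vector). Default: [select_public()] over the MS + CTRL blood
#'   samples of the ledger.
#' @param min_ms Minimum MS patients for rule A (default 5).
#' @param enrichment_fold Minimum MS/CTRL mean-proportion ratio for rule B
#'   (default 10).
#' @param pseudo Pseudocount added to both means for `log2_enrichment`;
#'   must be positive.
#' @return A tibble (`predominant_set`): `cdr3_aa`, occurrence counts
#'   `n_ms`/`n_ctrl`, group mean proportions, `rule`
#'   (`"ms_only_ge5"`/`"enriched_10x"`), `log2_enrichment`.
#' @export
select_predominant <- function(ledger, public = NULL, min_ms = 5L,
                               enrichment_fold = 10, pseudo = NULL) {
  stopifnot(inherits(ledger, "clone_ledger"))
  blood_samples <- ledger$samples |>
    dplyr::filter(.data$compartment == "blood", .data$group %in% c("MS", "CTRL"))
  public <- public %||% select_public(ledger, min_samples = 2L,
                                      sample_ids = blood_samples$sample_id)
  seqs <- if (is.data.frame(public)) public$cdr3_aa else public
  if (!length(seqs)) {
    return(tibble(cdr3_aa = character(), n_ms = integer(), n_ctrl = integer(),
                  mean_prop_ms = double(), mean_prop_ctrl = double(),
                  rule = character(), log2_enrichment = double()))
  }
  props <- clone_proportions(ledger, seqs, compartment = "blood")
  if (is.null(pseudo)) {
    nz <- props$proportion[props$proportion > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  if (pseudo <= 0) abort("`pseudo` must be positive.")
  summ <- props |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(
      n_ms = sum(.data$group == "MS" & .data$templates > 0L),
      n_ctrl = sum(.data$group == "CTRL" & .data$templates > 0L),
      mean_prop_ms = mean(.data$proportion[.data$group == "MS"]),
      mean_prop_ctrl = mean(.data$proportion[.data$group == "CTRL"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rule_a = .data$n_ms >= min_ms & .data$n_ctrl == 0L,
      rule_b = .data$n_ms > 0L & .data$n_ctrl > 0L &
        .data$mean_prop_ms >= enrichment_fold * .data$mean_prop_ctrl,
      log2_enrichment = log2((.data$mean_prop_ms + pseudo) /
                               (.data$mean_prop_ctrl + pseudo))
    ) |>
    dplyr::filter(.data$rule_a | .data$rule_b) |>
    dplyr::mutate(rule = ifelse(.data$rule_a, "ms_only_ge5", "enriched_10x")) |>
    dplyr::select("cdr3_aa", "n_ms", "n_ctrl", "mean_prop_ms",
                  "mean_prop_ctrl", "rule", "log2_enrichment")
  attr(summ, "pseudo") <- pseudo
  summ
}

#' Associate predominant sequences with cytokine levels
#'
#' For each (sequence, analyte) pair, correlates the sequence's blood clone
#' proportion across MS patients (0 when absent) with the patient's blood
#' cytokine concentration, using tie-corrected Kendall tau-b. Patients with
#' a not-detected cytokine are dropped pairwise. BH adjustment is applied
#' across all tested pairs jointly (one family); a pair is significant when
#' the adjusted p-value is below `alpha` and `|tau| > tau_min`.
#'
#' @param predominant A [select_predominant()] result (or character vector
#'   of sequences).
#' @param ledger A [clone_ledger()] covering MS blood.
#' @param panel Blood [cytokine_panel] with MS patient ids as sample names.
#' @param tau_min Absolute Kendall threshold (default 0.5).
#' @param alpha FDR threshold (default 0.05).
#' @param min_pairs Minimum complete pairs per test (default 5).
#' @param bh_scope `"global"` (one family across all pairs, default) or
#'   `"per_analyte"`.
#' @return An association tibble: `cdr3_aa`, `analyte`, `category`, `n`,
#'   `tau`, `raw_p`, `adjusted_p`, `significant`, `direction`,
#'   `log2_enrichment`, `rule`. Skipped pairs (too few pairs, constant
#'   inputs) are recorded in the `"skipped"` attribute.
#' @export
associate_cytokines <- function(predominant, ledger, panel, tau_min = 0.5,
                                alpha = 0.05, min_pairs = 5L,
                                bh_scope = c("global", "per_analyte")) {
  bh_scope <- match.arg(bh_scope)
  stopifnot(inherits(ledger, "clone_ledger"), inherits(panel, "cytokine_panel"))
  pred <- if (is.data.frame(predominant)) predominant else
    tibble(cdr3_aa = predominant, log2_enrichment = NA_real_, rule = NA_character_)
  if (!nrow(pred)) {
    out <- tibble(cdr3_aa = character(), analyte = character(), category = character(),
                  n = integer(), tau = double(), raw_p = double(),
                  adjusted_p = double(), significant = logical(),
                  direction = character(), log2_enrichment = double(),
                  rule = character())
    attr(out, "skipped") <- tibble(cdr3_aa = character(), analyte = character(),
                                   reason = character())
    return(out)
  }
  props <- clone_proportions(ledger, pred$cdr3_aa, compartment = "blood",
                             groups = "MS") |>
    dplyr::filter(.data$patient_id %in% rownames(panel$values))
  prop_wide <- props |>
    dplyr::select("cdr3_aa", "patient_id", "proportion") |>
    tidyr::pivot_wider(names_from = "patient_id", values_from = "proportion")
  patients <- setdiff(names(prop_wide), "cdr3_aa")
  v <- panel$values[patients, , drop = FALSE]
  prop_mat <- as.matrix(prop_wide[, patients])
  detected <- lapply(colnames(v), function(a) which(!is.na(v[, a])))
  names(detected) <- colnames(v)
  acc <- list(cdr3_aa = character(), analyte = character(), n = integer(),
              tau = double(), raw_p = double())
  skip <- list(cdr3_aa = character(), analyte = character(), reason = character())
  push <- function(env_list, ...) {
    vals <- list(...)
    for (nm in names(vals)) env_list[[nm]] <- c(env_list[[nm]], vals[[nm]])
    env_list
  }
  for (i in seq_len(nrow(prop_wide))) {
    sq <- prop_wide$cdr3_aa[i]
    x_all <- prop_mat[i, ]
    for (a in colnames(v)) {
      ok <- detected[[a]]
      if (length(ok) < min_pairs) {
        skip <- push(skip, cdr3_aa = sq, analyte = a,
                     reason = "too few detected pairs")
        next
      }
      kt <- kendall_tau_b(x_all[ok], v[ok, a], exact_max = 0L)
      if (is.na(kt$tau)) {
        skip <- push(skip, cdr3_aa = sq, analyte = a, reason = kt$reason)
        next
      }
      acc <- push(acc, cdr3_aa = sq, analyte = a, n = kt$n, tau = kt$tau,
                  raw_p = kt$p)
    }
  }
  out <- tibble::as_tibble(acc)
  skipped <- list(tibble::as_tibble(skip))
  if (nrow(out)) {
    if (bh_scope == "global") {
      out$adjusted_p <- bh_adjust(out$raw_p)
    } else {
      out <- out |>
        dplyr::group_by(.data$analyte) |>
        dplyr::mutate(adjusted_p = bh_adjust(.data$raw_p)) |>
        dplyr::ungroup()
    }
    out <- out |>
      dplyr::mutate(
        significant = .data$adjusted_p < alpha & abs(.data$tau) > tau_min,
        direction = ifelse(.data$tau >= 0, "+", "-"),
        category = unname(panel$categories[.data$analyte])
      ) |>
      dplyr::left_join(
        dplyr::select(pred, "cdr3_aa", dplyr::any_of(c("log2_enrichment", "rule"))),
        by = "cdr3_aa"
      ) |>
      dplyr::select("cdr3_aa", "analyte", "category", "n", "tau", "raw_p",
                    "adjusted_p", "significant", "direction",
                    dplyr::any_of(c("log2_enrichment", "rule")))
  }
  attr(out, "skipped") <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble(cdr3_aa = character(), analyte = character(), reason = character())
  out
}

#' Tabulate significant associations
#'
#' Counts significant positive and negative associations per analyte, sums
#' them per functional category (with a grand-total row), and ranks
#' sequences by the number of cytokines they associate with.
#'
#' @param associations An [associate_cytokines()] result.
#' @param min_cytokines Threshold for the multi-cytokine sequence list
#'   (default 3).
#' @return List with `by_analyte`, `by_category` (including a `"total"`
#'   row), and `multi` (sequences associating with at least
#'   `min_cytokines` cytokines).
#' @export
tabulate_associations <- function(associations, min_cytokines = 3L) {
  sig <- dplyr::filter(associations, .data$significant)
  by_analyte <- sig |>
    dplyr::group_by(.data$analyte, .data$category) |>
    dplyr::summarise(positive = sum(.data$direction == "+"),
                     negative = sum(.data$direction == "-"),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$positive + .data$negative))
  by_category <- by_analyte |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(positive = sum(.data$positive),
                     negative = sum(.data$negative), .groups = "drop")
  by_category <- dplyr::bind_rows(
    by_category,
    tibble(category = "total",
           positive = sum(by_category$positive),
           negative = sum(by_category$negative))
  )
  multi <- sig |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(n_cytokines = dplyr::n_distinct(.data$analyte),
                     analytes = paste(sort(unique(.data$analyte)), collapse = ","),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cytokines >= min_cytokines) |>
    dplyr::arrange(dplyr::desc(.data$n_cytokines))
  list(by_analyte = by_analyte, by_category = by_category, multi = multi)
}
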