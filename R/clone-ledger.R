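# CloneLedger: cohort-wide CDR3 amino-acid index. Clone counts of identical
# CDR3.aa with different clonotypes (nucleotide sequence / V-J calls) are
# summed per (patient, compartment); non-productive rows are excluded by
# default.

#' Aggregate rearrangements into a clone ledger
#'
#' Collapses clonotypes to CDR3 amino-acid identity: within each
#' (patient, compartment) sample, template counts of rows sharing a CDR3.aa
#' are summed. Per-sample totals (total templates including non-productive
#' rows, productive templates, productive rearrangements, distinct CDR3.aa)
#' are kept alongside.
#'
#' @param rearrangements Long tibble of rearrangement rows with columns
#'   `sample_id`, `patient_id`, `compartment`, `group`, `cdr3_aa`,
#'   `templates`, `productive` (the shape produced by
#'   [generate_repertoires()] or by binding [read_rearrangements()] outputs
#'   joined to sample metadata).
#' @param productive_only Drop non-productive rows before aggregation
#'   (default `TRUE`).
#' @return A `clone_ledger`: list with `clones` (cdr3_aa, patient_id,
#'   compartment, group, sample_id, templates) and `samples` (per-sample
#'   totals).
#' @export
clone_ledger <- function(rearrangements, productive_only = TRUE) {
  need <- c("sample_id", "patient_id", "compartment", "group", "cdr3_aa",
            "templates", "productive")
  missing <- setdiff(need, names(rearrangements))
  if (length(missing)) {
    abort(paste0("`rearrangements` is missing columns: ", paste(missing, collapse = ", ")))
  }
  dup <- rearrangements |>
    dplyr::distinct(.data$sample_id, .data$patient_id, .data$compartment) |>
    dplyr::count(.data$patient_id, .data$compartment) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate (patient, compartment) sample: %s / %s",
                  dup$patient_id[1], dup$compartment[1]))
  }
  # data.table aggregation: cohort-scale inputs run to millions of rows
  dt <- data.table::as.data.table(rearrangements[, need])
  samples <- tibble::as_tibble(dt[, list(
    total_templates = sum(templates),
    productive_templates = sum(templates[productive]),
    productive_rearrangements = sum(productive),
    n_unique_cdr3aa = data.table::uniqueN(cdr3_aa[productive])
  ), by = c("sample_id", "patient_id", "compartment", "group")])
  kept <- if (productive_only) dt[productive == TRUE] else dt
  clones <- tibble::as_tibble(kept[, list(templates = sum(templates)),
                                   by = c("cdr3_aa", "patient_id", "compartment",
                                          "group", "sample_id")])
  clones <- clones[clones$templates > 0L, ]
  structure(list(clones = clones, samples = samples,
                 productive_only = productive_only),
            class = "clone_ledger")
}

#' @export
print.clone_ledger <- function(x, ...) {
  cat(sprintf("<clone_ledger> %d samples, %d (clone, sample) records, %d distinct CDR3.aa\n",
              nrow(x$samples), nrow(x$clones), dplyr::n_distinct(x$clones$cdr3_aa)))
  invisible(x)
}

#' Classify clones as unique/shared and private/public
#'
#' Per patient, a clone (CDR3.aa) found in both CSF and blood is *shared*;
#' found in exactly one compartment it is *unique*. Orthogonally, a clone
#' found in more than one individual is *public*, otherwise *private*.
#'
#' @param ledger A [clone_ledger()].
#' @return Tibble with one row per (clone, patient): `cdr3_aa`,
#'   `patient_id`, `group`, `n_compartments`, `sharing`
#'   (`"shared"`/`"unique"`), `public` (logical, cohort-wide).
#' @export
classify_clones <- function(ledger) {
  stopifnot(inherits(ledger, "clone_ledger"))
  per_patient <- ledger$clones |>
    dplyr::group_by(.data$cdr3_aa, .data$patient_id, .data$group) |>
    dplyr::summarise(n_compartments = dplyr::n_distinct(.data$compartment),
                     .groups = "drop") |>
    dplyr::mutate(sharing = ifelse(.data$n_compartments > 1L, "shared", "unique"))
  publicity <- per_patient |>
    dplyr::count(.data$cdr3_aa, name = "n_patients")
  per_patient |>
    dplyr::left_join(publicity, by = "cdr3_aa") |>
    dplyr::mutate(public = .data$n_patients > 1L)
}
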