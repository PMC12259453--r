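# Cohort serialization: immunoSEQ-dialect TSVs per sample, cytokine CSVs,
# metadata CSV, ground-truth JSON, and a manifest for reproducible runs.

#' Write a synthetic cohort to disk
#'
#' Layout: `repertoires/<sample_id>.tsv` (immunoSEQ dialect), and
#' `cytokines_csf.csv`, `cytokines_blood.csv`, `metadata.csv`,
#' `ground_truth.json`, `manifest.tsv` at the top level.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`file`, `n_rows`), invisibly written to
#'   `manifest.tsv` as well.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  dir.create(file.path(dir, "repertoires"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory '%s'.", dir))
  manifest <- list()
  rr <- cohort$rearrangements
  if (is.null(rr) || nrow(rr) == 0L) {
    warn("empty cohort: writing metadata only.")
  } else {
    for (sid in unique(rr$sample_id)) {
      sub <- rr[rr$sample_id == sid, ]
      rel <- file.path("repertoires", paste0(sid, ".tsv"))
      write_rearrangements(sub, file.path(dir, rel))
      manifest[[length(manifest) + 1L]] <- tibble(file = rel, n_rows = nrow(sub))
    }
  }
  for (comp in c("csf", "blood")) {
    p <- cohort$cytokines[[comp]]
    if (!is.null(p)) {
      rel <- sprintf("cytokines_%s.csv", comp)
      write_cytokines(p, file.path(dir, rel))
      manifest[[length(manifest) + 1L]] <- tibble(file = rel, n_rows = nrow(p$values))
    }
  }
  readr::write_csv(cohort$metadata$patients, file.path(dir, "metadata.csv"),
                   na = "", progress = FALSE)
  manifest[[length(manifest) + 1L]] <- tibble(file = "metadata.csv",
                                              n_rows = nrow(cohort$metadata$patients))
  gt <- cohort$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  manifest_tb <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest_tb, file.path(dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest_tb)
}

#' Read a cohort directory back
#'
#' Counterpart of [write_cohort()]: loads metadata, both cytokine panels
#' and all rearrangement tables (joined to sample metadata) into the
#' in-memory cohort shape.
#'
#' @param dir Cohort directory.
#' @return A `tcr_cohort`-like list with `metadata`, `cytokines` and
#'   `rearrangements` (and `ground_truth` when present on disk).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    abort(sprintf("missing artifact: %s", meta_path))
  }
  patients <- read_metadata(meta_path)
  samples <- dplyr::bind_rows(
    patients |> dplyr::filter(.data$has_csf) |>
      dplyr::transmute(patient_id = .data$patient_id, group = .data$group,
                       compartment = "CSF"),
    patients |> dplyr::filter(.data$has_blood) |>
      dplyr::transmute(patient_id = .data$patient_id, group = .data$group,
                       compartment = "blood")
  ) |>
    dplyr::mutate(sample_id = paste(.data$patient_id, .data$compartment, sep = "_")) |>
    dplyr::arrange(.data$patient_id, .data$compartment)
  cytokines <- list()
  for (comp in c("csf", "blood")) {
    p <- file.path(dir, sprintf("cytokines_%s.csv", comp))
    if (file.exists(p)) cytokines[[comp]] <- read_cytokines(p)
  }
  rep_dir <- file.path(dir, "repertoires")
  files <- if (dir.exists(rep_dir)) sort(list.files(rep_dir, pattern = "\\.tsv$",
                                                    full.names = TRUE)) else character()
  rearrangements <- NULL
  if (length(files)) {
    tabs <- lapply(files, read_rearrangements)
    rearrangements <- dplyr::bind_rows(tabs) |>
      dplyr::left_join(samples, by = "sample_id")
    missing <- unique(rearrangements$sample_id[is.na(rearrangements$group)])
    if (length(missing)) {
      abort(paste0("repertoire files without metadata entry: ",
                   paste(missing, collapse = ", ")))
    }
  }
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) jsonlite::read_json(gt_path, simplifyVector = TRUE) else NULL
  structure(list(metadata = list(patients = patients, samples = samples),
                 cytokines = cytokines, rearrangements = rearrangements,
                 ground_truth = ground_truth),
            class = "tcr_cohort")
}
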