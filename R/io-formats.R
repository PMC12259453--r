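# Readers and writers for the external formats the pipeline touches:
# immunoSEQ-dialect rearrangement TSVs, cytokine panel CSVs, cohort
# metadata, GraphML / edge-list network exports, and sequence annotation.

rearrangement_cols <- c("rearrangement", "amino_acid", "v_gene", "d_gene",
                        "j_gene", "templates", "frame_type")

#' Read an immunoSEQ-dialect rearrangement table
#'
#' Reads one sample's rearrangements from a tab-delimited file with the
#' columns `rearrangement` (CDR3 nucleotide sequence), `amino_acid`,
#' `v_gene`, `d_gene`, `j_gene`, `templates`, `frame_type`. Real exports
#' carry many more columns; unknown extras are preserved untouched.
#' `productive` is derived from `frame_type` (`"In"` means in-frame).
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return Tibble with `sample_id`, the seven dialect columns renamed to
#'   `cdr3_nt`, `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`, `templates`,
#'   `frame_type`, a derived logical `productive`, and any extra columns.
#'   Row order is preserved.
#' @export
read_rearrangements <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(rearrangement_cols, names(tb))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  templates <- suppressWarnings(as.numeric(tb$templates))
  bad <- which(is.na(templates) | templates < 0 | templates != round(templates))
  if (length(bad)) {
    abort(sprintf("%s: invalid template count '%s' at data row %d.",
                  basename(path), tb$templates[bad[1]], bad[1]))
  }
  empty_aa <- which(tb$frame_type == "In" & (is.na(tb$amino_acid) | tb$amino_acid == ""))
  if (length(empty_aa)) {
    abort(sprintf("%s: empty amino_acid on productive row %d.",
                  basename(path), empty_aa[1]))
  }
  out <- tb
  names(out)[match(c("rearrangement", "amino_acid"), names(out))] <- c("cdr3_nt", "cdr3_aa")
  out$templates <- as.integer(templates)
  out$productive <- out$frame_type == "In"
  dplyr::bind_cols(tibble(sample_id = rep(sample_id, nrow(out))), out)
}

#' Write an immunoSEQ-dialect rearrangement table
#'
#' @param rearrangements Tibble with columns `cdr3_nt`, `cdr3_aa`, `v_gene`,
#'   `d_gene`, `j_gene`, `templates`, `frame_type` (one sample).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rearrangements, path) {
  out <- tibble(
    rearrangement = rearrangements$cdr3_nt,
    amino_acid = rearrangements$cdr3_aa,
    v_gene = rearrangements$v_gene,
    d_gene = rearrangements$d_gene,
    j_gene = rearrangements$j_gene,
    templates = rearrangements$templates,
    frame_type = rearrangements$frame_type
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a cytokine panel CSV
#'
#' The expected layout is one row per sample: first column the sample id,
#' remaining columns one analyte each. Empty cells mean "not detected";
#' numeric cells must be non-negative concentrations. Analyte names are
#' canonicalised via [canonicalize_analyte()].
#'
#' @param path Path to the CSV file.
#' @param categories Analyte category map; every analyte column must be
#'   covered (default [cytokine_categories]).
#' @return A [cytokine_panel].
#' @export
read_cytokines <- function(path, categories = cytokine_categories) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(tb) < 2L) abort(sprintf("%s: expected sample id plus analyte columns.", basename(path)))
  ids <- tb[[1]]
  analytes <- canonicalize_analyte(names(tb)[-1])
  vals <- sapply(tb[-1], function(col) suppressWarnings(as.numeric(col)))
  vals <- matrix(vals, nrow = nrow(tb),
                 dimnames = list(ids, analytes))
  raw_nonempty <- sapply(tb[-1], function(col) !(is.na(col) | col == ""))
  bad <- which(is.na(vals) & raw_nonempty, arr.ind = TRUE)
  if (length(bad)) {
    abort(sprintf("%s: non-numeric concentration at row %d, analyte '%s'.",
                  basename(path), bad[1, 1], analytes[bad[1, 2]]))
  }
  if (any(vals < 0, na.rm = TRUE)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative concentration at row %d, analyte '%s'.",
                  basename(path), bad[1], analytes[bad[2]]))
  }
  cytokine_panel(vals, categories = categories)
}

#' Write a cytokine panel CSV
#'
#' Not-detected cells are written as empty strings.
#'
#' @param panel A [cytokine_panel].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cytokines <- function(panel, path) {
  stopifnot(inherits(panel, "cytokine_panel"))
  df <- as.data.frame(panel$values)
  df <- cbind(sample_id = rownames(panel$values), df)
  readr::write_csv(tibble::as_tibble(df), path, na = "", progress = FALSE)
  invisible(path)
}

#' Export a cytokine network
#'
#' Writes either GraphML (via igraph; nodes carry the `category` attribute,
#' edges carry `r`, `adjusted_p` and `sign`) or a plain edge TSV sorted by
#' `|r|` descending for reproducible diffs.
#'
#' @param network A [build_network()] result.
#' @param path Output path.
#' @param dialect `"graphml"` or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("graphml", "edge_tsv")) {
  stopifnot(inherits(network, "cytokine_network"))
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    readr::write_tsv(network$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Annotate CDR3 sequences against a user-supplied table
#'
#' Labels sequences by exact full-string CDR3 amino-acid match against an
#' annotation table (e.g. a disease-association export the user obtained
#' themselves). Non-matches get the label `"none"`.
#'
#' @param sequences Character vector of CDR3 amino-acid sequences, or a
#'   data frame with a `cdr3_aa` column.
#' @param annotation Data frame with columns `cdr3_aa` and `label`, or a
#'   path to a TSV with those columns.
#' @return The input as a tibble with an `annotation` column appended.
#' @export
annotate_sequences <- function(sequences, annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- readr::read_tsv(annotation, col_types = readr::cols(.default = readr::col_character()),
                                  progress = FALSE)
  }
  if (!all(c("cdr3_aa", "label") %in% names(annotation))) {
    abort("`annotation` must have columns `cdr3_aa` and `label`.")
  }
  dup <- annotation |>
    dplyr::distinct(.data$cdr3_aa, .data$label) |>
    dplyr::count(.data$cdr3_aa) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(paste0("conflicting labels for: ", paste(dup$cdr3_aa, collapse = ", ")))
  }
  ann <- dplyr::distinct(annotation, .data$cdr3_aa, .data$label)
  tb <- if (is.data.frame(sequences)) tibble::as_tibble(sequences) else tibble(cdr3_aa = sequences)
  tb |>
    dplyr::left_join(ann, by = "cdr3_aa") |>
    dplyr::mutate(annotation = dplyr::coalesce(.data$label, "none")) |>
    dplyr::select(-"label")
}

#' Read cohort metadata CSV
#'
#' @param path CSV with columns `patient_id`, `group`, `hla_drb1_1501`,
#'   `age`, `sex`, `edss`, `has_blood`, `has_csf`.
#' @return Tibble of patient metadata.
#' @export
read_metadata <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    group = readr::col_character(),
    hla_drb1_1501 = readr::col_logical(),
    age = readr::col_double(),
    sex = readr::col_character(),
    edss = readr::col_double(),
    has_blood = readr::col_logical(),
    has_csf = readr::col_logical()
  ), progress = FALSE)
  if (!all(tb$group %in% c("MS", "CTRL", "HEALTHY_REF"))) {
    abort("`group` must be one of MS, CTRL, HEALTHY_REF.")
  }
  tb
}
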