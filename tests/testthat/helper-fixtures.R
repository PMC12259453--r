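# In-code fixtures: toy rearrangement tables, tiny panels, and a reduced
# cohort configuration for fast end-to-end tests.

# expand a compact clone spec into a full rearrangement tibble
toy_rearrangements <- function(spec) {
  spec <- tibble::as_tibble(spec)
  defaults <- tibble::tibble(
    group = "MS", templates = 1L, productive = TRUE,
    v_gene = "TRBV28-1", d_gene = "TRBD1-1", j_gene = "TRBJ1-1"
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(spec)) spec[[nm]] <- defaults[[nm]]
  }
  spec$sample_id <- paste(spec$patient_id, spec$compartment, sep = "_")
  spec$cdr3_nt <- chartr("ACDEFGHIKLMNPQRSTVWY", "ACGTACGTACGTACGTACGT", spec$cdr3_aa)
  spec$frame_type <- ifelse(spec$productive, "In", "Out")
  spec$templates <- as.integer(spec$templates)
  spec[, c("sample_id", "patient_id", "compartment", "group", "cdr3_nt",
           "cdr3_aa", "v_gene", "d_gene", "j_gene", "templates", "frame_type",
           "productive")]
}

toy_ledger <- function(spec) {
  clone_ledger(toy_rearrangements(spec))
}

# small samples x analytes panel; NA marks not-detected cells
toy_panel <- function(values, analytes = NULL, samples = NULL) {
  if (is.null(analytes)) analytes <- head(cytokine_categories$analyte, ncol(values))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(values)))
  dimnames(values) <- list(samples, analytes)
  cytokine_panel(values)
}

# a cohort small enough for subsecond simulation
small_cohort_config <- function(...) {
  defaults <- list(n_healthy_ref = 8L, clones_per_blood = 300L,
                   clones_per_csf = 100L, clones_per_healthy = 150L,
                   blood_templates = 3000L, csf_templates = 800L)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
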