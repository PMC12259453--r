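# End-to-end orchestration: simulate -> cytokines -> network -> repertoire
# -> prs -> integrate, with file artifacts per stage, fail-fast input
# checks, audit logging of every exclusion, and a machine-readable report.

#' Configure a pipeline run
#'
#' All thresholds default to the values of the emulated analysis protocol,
#' so a bare run reproduces the full procedure on synthetic data.
#'
#' @param outdir Output directory for artifacts.
#' @param seed Integer seed driving the simulation and all seeded stages.
#' @param cohort A [cohort_config()]; defaults to `cohort_config(seed = seed)`.
#' @param r_min,alpha,tau_min,top_n,min_count,min_patients,min_ms,
#'   enrichment_fold,winsor_tail,outlier_k,sample_flag_fraction,min_pairs
#'   Stage thresholds (see the stage functions for semantics).
#' @param productive_only Restrict clone accounting to productive rows.
#' @param bh_scope BH family for the association stage (`"global"` or
#'   `"per_analyte"`).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("tcrcyto_run_"), seed = 1L,
                            cohort = NULL,
                            r_min = 0.6, alpha = 0.05, tau_min = 0.5,
                            top_n = 10L, min_count = 2L, min_patients = 2L,
                            min_ms = 5L, enrichment_fold = 10,
                            winsor_tail = 0.125, outlier_k = 2,
                            sample_flag_fraction = 0.25, min_pairs = 5L,
                            productive_only = TRUE,
                            bh_scope = c("global", "per_analyte")) {
  bh_scope <- match.arg(bh_scope)
  seed <- assert_count(seed, "seed", 0L)
  if (!is.numeric(r_min) || r_min < 0 || r_min > 1) abort("`r_min` must lie in [0, 1].")
  assert_fraction(alpha, "alpha")
  if (tau_min < 0 || tau_min > 1) abort("`tau_min` must lie in [0, 1].")
  if (winsor_tail < 0 || winsor_tail >= 0.5) abort("`winsor_tail` must lie in [0, 0.5).")
  if (outlier_k <= 0) abort("`outlier_k` must be positive.")
  assert_fraction(sample_flag_fraction, "sample_flag_fraction")
  if (enrichment_fold <= 1) abort("`enrichment_fold` must exceed 1.")
  for (nm in c("top_n", "min_count", "min_patients", "min_ms", "min_pairs")) {
    assert_count(get(nm), nm, 1L)
  }
  cohort <- cohort %||% cohort_config(seed = seed)
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(
    outdir = outdir, seed = seed, cohort = cohort,
    r_min = r_min, alpha = alpha, tau_min = tau_min,
    top_n = as.integer(top_n), min_count = as.integer(min_count),
    min_patients = as.integer(min_patients), min_ms = as.integer(min_ms),
    enrichment_fold = enrichment_fold, winsor_tail = winsor_tail,
    outlier_k = outlier_k, sample_flag_fraction = sample_flag_fraction,
    min_pairs = as.integer(min_pairs), productive_only = productive_only,
    bh_scope = bh_scope
  ), class = "pipeline_config")
}

pipeline_stages <- c("simulate", "cytokines", "network", "repertoire",
                     "prs", "integrate")

log_line <- function(verbose, ...) if (verbose) inform(paste0("[tcrcyto] ", sprintf(...)))

require_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("stage '%s': missing input artifact '%s' (run stage '%s' first).",
                  stage, path, produced_by))
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in fixed order, writing each stage's
#' artifacts into its own subdirectory of `config$outdir` and assembling a
#' machine-readable `report.json`. Later stages read earlier stages'
#' artifacts from disk and fail fast, naming the missing file, when a
#' prerequisite has not been produced. Every exclusion the analysis makes
#' (skipped analytes, removed outlier samples, unpaired patients) is
#' logged.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages, or `"all"` (default). Stages:
#'   `simulate`, `cytokines`, `network`, `repertoire`, `prs`, `integrate`.
#' @param verbose Emit progress/log messages (default `TRUE`).
#' @return The report (named list), invisibly; also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(config$outdir, "report.json")
  report <- if (file.exists(report_path)) {
    jsonlite::read_json(report_path, simplifyVector = TRUE)
  } else {
    list(package_version = as.character(utils::packageVersion("tcrcyto")),
         seed = config$seed, stages = list())
  }
  for (st in stages) {
    log_line(verbose, "stage %s", st)
    report$stages[[st]] <- switch(
      st,
      simulate = stage_simulate(config, verbose),
      cytokines = stage_cytokines(config, verbose),
      network = stage_network(config, verbose),
      repertoire = stage_repertoire(config, verbose),
      prs = stage_prs(config, verbose),
      integrate = stage_integrate(config, verbose)
    )
  }
  report$config <- config[setdiff(names(config), c("cohort", "outdir"))]
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(report)
}

stage_simulate <- function(config, verbose) {
  cohort <- simulate_cohort(config$cohort)
  manifest <- write_cohort(cohort, file.path(config$outdir, "cohort"))
  log_line(verbose, "simulated %d samples (%d files)",
           nrow(cohort$metadata$samples), nrow(manifest))
  list(n_samples = nrow(cohort$metadata$samples),
       n_rearrangement_rows = nrow(cohort$rearrangements),
       n_files = nrow(manifest))
}

load_cohort_artifacts <- function(config, stage) {
  dir <- file.path(config$outdir, "cohort")
  require_artifact(file.path(dir, "metadata.csv"), stage, "simulate")
  read_cohort(dir)
}

stage_cytokines <- function(config, verbose) {
  cohort <- load_cohort_artifacts(config, "cytokines")
  dir <- file.path(config$outdir, "cytokines")
  dir.create(dir, showWarnings = FALSE)
  out <- list()
  for (comp in c("csf", "blood")) {
    panel <- cohort$cytokines[[comp]]
    if (is.null(panel)) next
    pats <- cohort$metadata$patients
    groups <- setNames(pats$group, pats$patient_id)
    groups <- groups[groups %in% c("MS", "CTRL")]
    groups <- groups[names(groups) %in% rownames(panel$values)]
    suppressWarnings(
      outliers <- detect_outliers(panel_subset(panel, names(groups)), groups,
                                  k = config$outlier_k,
                                  sample_flag_fraction = config$sample_flag_fraction)
    )
    for (s in outliers$removed_samples) {
      log_line(verbose, "%s: sample %s removed as outlier", comp, s)
    }
    cmp <- compare_cytokine_groups(panel, groups, test = "mann_whitney",
                                   alpha = config$alpha, reference = "CTRL",
                                   exclude_samples = outliers$removed_samples)
    for (s in attr(cmp, "skipped")) {
      log_line(verbose, "%s: analyte %s skipped in group comparison", comp, s)
    }
    readr::write_tsv(cmp, file.path(dir, sprintf("comparison_%s.tsv", comp)),
                     progress = FALSE)
    # per-group processed matrices feed the network stage and the heatmap
    for (g in c("MS", "CTRL")) {
      ids <- setdiff(names(groups)[groups == g], outliers$removed_samples)
      suppressWarnings(prep <- preprocess_cytokines(
        panel, ids, k = config$outlier_k,
        sample_flag_fraction = config$sample_flag_fraction,
        tail_prob = config$winsor_tail))
      m <- prep$matrix
      readr::write_tsv(
        tibble::as_tibble(cbind(data.frame(sample_id = rownames(m)), m)),
        file.path(dir, sprintf("processed_%s_%s.tsv", g, comp)), na = "",
        progress = FALSE)
      # z-scored analyte rows for heatmap reproduction
      suppressWarnings(z <- zscore_rows(t(m)))
      readr::write_tsv(
        tibble::as_tibble(cbind(data.frame(analyte = rownames(z)), z)),
        file.path(dir, sprintf("zscore_%s_%s.tsv", g, comp)), na = "",
        progress = FALSE)
    }
    out[[comp]] <- list(n_tested = nrow(cmp),
                        n_significant = sum(cmp$significant),
                        removed_samples = outliers$removed_samples)
  }
  out
}

stage_network <- function(config, verbose) {
  dir <- file.path(config$outdir, "network")
  dir.create(dir, showWarnings = FALSE)
  out <- list()
  for (comp in c("csf", "blood")) {
    for (g in c("MS", "CTRL")) {
      path <- file.path(config$outdir, "cytokines",
                        sprintf("processed_%s_%s.tsv", g, comp))
      require_artifact(path, "network", "cytokines")
      tb <- readr::read_tsv(path, col_types = readr::cols(
        sample_id = readr::col_character(), .default = readr::col_double()),
        progress = FALSE)
      m <- as.matrix(tb[, -1])
      rownames(m) <- tb$sample_id
      pairs <- pearson_all_pairs(m, min_pairs = 4L)
      if (nrow(pairs)) pairs$adjusted_p <- bh_adjust(pairs$raw_p)
      net <- build_network(pairs, r_min = config$r_min, alpha = config$alpha,
                           analytes = colnames(m))
      write_network(net, file.path(dir, sprintf("network_%s_%s.graphml", g, comp)),
                    dialect = "graphml")
      write_network(net, file.path(dir, sprintf("edges_%s_%s.tsv", g, comp)),
                    dialect = "edge_tsv")
      coords <- layout_force_directed(net, seed = config$seed)
      readr::write_tsv(coords, file.path(dir, sprintf("layout_%s_%s.tsv", g, comp)),
                       progress = FALSE)
      s <- network_summary(net)
      jsonlite::write_json(
        list(n_nodes = s$n_nodes, n_edges = s$n_edges,
             n_positive = s$n_positive, n_negative = s$n_negative,
             n_components = s$n_components),
        file.path(dir, sprintf("summary_%s_%s.json", g, comp)),
        auto_unbox = TRUE, digits = NA)
      out[[sprintf("%s_%s", g, comp)]] <- list(n_edges = s$n_edges,
                                               n_positive = s$n_positive,
                                               n_negative = s$n_negative)
      log_line(verbose, "network %s/%s: %d edges", g, comp, s$n_edges)
    }
  }
  out
}

stage_repertoire <- function(config, verbose) {
  cohort <- load_cohort_artifacts(config, "repertoire")
  if (is.null(cohort$rearrangements)) {
    abort("stage 'repertoire': missing input artifact 'cohort/repertoires/' (run stage 'simulate' first).")
  }
  dir <- file.path(config$outdir, "repertoire")
  dir.create(dir, showWarnings = FALSE)
  ledger <- clone_ledger(cohort$rearrangements,
                         productive_only = config$productive_only)
  stats <- sample_statistics(ledger)
  readr::write_tsv(stats$samples, file.path(dir, "sample_statistics.tsv"),
                   progress = FALSE)
  readr::write_tsv(stats$tests, file.path(dir, "sample_statistic_tests.tsv"),
                   progress = FALSE)
  sh <- sharing_summary(ledger)
  for (p in sh$excluded$patient_id) {
    log_line(verbose, "sharing: patient %s excluded (missing pair)", p)
  }
  readr::write_tsv(sh$patients, file.path(dir, "sharing.tsv"), progress = FALSE)
  if (!is.null(sh$tests)) {
    readr::write_tsv(sh$tests, file.path(dir, "sharing_tests.tsv"), progress = FALSE)
  }
  usage <- trbv_usage(cohort$rearrangements,
                      productive_only = config$productive_only,
                      alpha = config$alpha)
  readr::write_tsv(usage$proportions, file.path(dir, "trbv_proportions.tsv"),
                   progress = FALSE)
  readr::write_tsv(usage$tests, file.path(dir, "trbv_tests.tsv"), progress = FALSE)
  # HLA carriage 2x2 among typed patients
  pats <- cohort$metadata$patients
  typed <- pats[!is.na(pats$hla_drb1_1501) & pats$group %in% c("MS", "CTRL"), ]
  fisher <- NULL
  if (nrow(typed)) {
    tab <- matrix(c(sum(typed$group == "MS" & typed$hla_drb1_1501),
                    sum(typed$group == "MS" & !typed$hla_drb1_1501),
                    sum(typed$group == "CTRL" & typed$hla_drb1_1501),
                    sum(typed$group == "CTRL" & !typed$hla_drb1_1501)),
                  nrow = 2, byrow = TRUE)
    fisher <- fisher_2x2(tab)
    readr::write_tsv(fisher, file.path(dir, "hla_fisher.tsv"), progress = FALSE)
  }
  list(n_samples = nrow(stats$samples),
       n_paired_patients = nrow(sh$patients),
       sharing_p_csf_direction = if (!is.null(sh$tests))
         sh$tests$p_value[sh$tests$direction == "pct_shared_of_csf"] else NA,
       hla_fisher_p = if (!is.null(fisher)) fisher$p_value else NA)
}

stage_prs <- function(config, verbose) {
  cohort <- load_cohort_artifacts(config, "prs")
  if (is.null(cohort$rearrangements)) {
    abort("stage 'prs': missing input artifact 'cohort/repertoires/' (run stage 'simulate' first).")
  }
  dir <- file.path(config$outdir, "prs")
  dir.create(dir, showWarnings = FALSE)
  ledger <- clone_ledger(cohort$rearrangements,
                         productive_only = config$productive_only)
  prs <- identify_prs(ledger, top_n = config$top_n, min_count = config$min_count,
                      min_patients = config$min_patients)
  readr::write_tsv(prs, file.path(dir, "prs.tsv"), progress = FALSE)
  counts <- attr(prs, "counts")
  log_line(verbose, "PRS: %d criterion-1, %d criterion-2, union %d",
           counts[["criterion1"]], counts[["criterion2"]], counts[["union"]])
  out <- list(n_prs = nrow(prs), n_criterion1 = unname(counts[["criterion1"]]),
              n_criterion2 = unname(counts[["criterion2"]]))
  if (nrow(prs) >= 2L) {
    rm_mat <- build_rank_matrix(prs, ledger)
    ms_samples <- intersect(colnames(rm_mat),
                            ledger$samples$sample_id[ledger$samples$group == "MS"])
    cl <- kmeans_two(rm_mat, ms_samples, seed = config$seed)
    readr::write_tsv(tidy(cl), file.path(dir, "clusters.tsv"), progress = FALSE)
    pc <- pca_project(rm_mat)
    readr::write_tsv(pc$coords, file.path(dir, "pca.tsv"), progress = FALSE)
    occ_test <- cluster_occurrence_test(cl)
    readr::write_tsv(occ_test, file.path(dir, "occurrence_test.tsv"),
                     progress = FALSE)
    out$n_ms_associated <- sum(cl$assignment$label == "ms_associated")
    out$occurrence_p_ms_cluster <-
      occ_test$p_value[occ_test$label == "ms_associated"]
  }
  out
}

stage_integrate <- function(config, verbose) {
  cohort <- load_cohort_artifacts(config, "integrate")
  if (is.null(cohort$rearrangements)) {
    abort("stage 'integrate': missing input artifact 'cohort/repertoires/' (run stage 'simulate' first).")
  }
  if (is.null(cohort$cytokines$blood)) {
    abort("stage 'integrate': missing input artifact 'cohort/cytokines_blood.csv'.")
  }
  dir <- file.path(config$outdir, "integrate")
  dir.create(dir, showWarnings = FALSE)
  ledger <- clone_ledger(cohort$rearrangements,
                         productive_only = config$productive_only)
  blood_ids <- ledger$samples$sample_id[
    ledger$samples$compartment == "blood" &
      ledger$samples$group %in% c("MS", "CTRL")]
  public <- select_public(ledger, min_samples = config$min_patients,
                          sample_ids = blood_ids)
  pred <- select_predominant(ledger, public = public, min_ms = config$min_ms,
                             enrichment_fold = config$enrichment_fold)
  readr::write_tsv(pred, file.path(dir, "predominant.tsv"), progress = FALSE)
  assoc <- associate_cytokines(pred, ledger, cohort$cytokines$blood,
                               tau_min = config$tau_min, alpha = config$alpha,
                               min_pairs = config$min_pairs,
                               bh_scope = config$bh_scope)
  readr::write_tsv(assoc, file.path(dir, "associations.tsv"), progress = FALSE)
  tab <- tabulate_associations(assoc)
  readr::write_tsv(tab$by_analyte, file.path(dir, "tally_by_analyte.tsv"),
                   progress = FALSE)
  readr::write_tsv(tab$by_category, file.path(dir, "tally_by_category.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(n_public = nrow(public), n_predominant = nrow(pred),
         n_tested = nrow(assoc), n_significant = sum(assoc$significant),
         n_sequences_significant =
           dplyr::n_distinct(assoc$cdr3_aa[assoc$significant]),
         n_cytokines_significant =
           dplyr::n_distinct(assoc$analyte[assoc$significant])),
    file.path(dir, "tally.json"), auto_unbox = TRUE, digits = NA)
  log_line(verbose, "integrate: %d public, %d predominant, %d significant associations",
           nrow(public), nrow(pred), sum(assoc$significant))
  list(n_public = nrow(public), n_predominant = nrow(pred),
       n_associations_tested = nrow(assoc),
       n_associations_significant = sum(assoc$significant))
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed; keys are the arguments of [pipeline_config()] (unknown keys are
#' rejected). Values are parsed as numbers or logicals where possible.
#'
#' @param path Path to the configuration file.
#' @param ... Overrides passed straight to [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("cannot parse config line: '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- setdiff(names(formals(pipeline_config)), c("cohort", "..."))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  parse_val <- function(v) {
    if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  args <- setNames(lapply(vals, parse_val), keys)
  do.call(pipeline_config, utils::modifyList(args, list(...)))
}
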