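# Configuration of the synthetic study: cohort sizes, clone-size law,
# planted cytokine structure (group fold changes, correlation blocks),
# planted sequence-cytokine links and cluster sequences, detection limits.

#' Default planted sequence-cytokine links
#'
#' Three synthetic CDR3.aa sequences, each tied to one blood analyte with a
#' target Kendall tau of 0.7 via a Gaussian copula on ranks.
#'
#' @return Tibble with columns `sequence`, `analyte`, `tau`.
#' @export
default_planted_links <- function() {
  tibble(
    sequence = encode_cdr3(link_id_base + 1:3)$aa,
    analyte = c("TNF-b", "SCF", "Eotaxin"),
    tau = 0.7
  )
}

# reserved id ranges for the deterministic CDR3 encoding
link_id_base <- 10000000L
ms_cluster_id_base <- 10100000L
general_id_base <- 10200000L
private_id_base <- 1000000L

#' Configure a synthetic cohort
#'
#' Collects every knob of the synthetic study in one validated object. The
#' defaults describe the emulated study design: 24 MS patients and 9
#' non-inflammatory controls with paired CSF and blood, an 88-donor
#' healthy blood reference cohort, a 48-analyte cytokine panel with two
#' planted CSF fold changes (2.57 and 1.91), one planted 4-analyte
#' correlation block at r = 0.9, power-law clone sizes, CSF-to-blood clone
#' sharing of 0.5% (MS) vs 0.1% (controls), and three sequence-cytokine
#' links planted at Kendall tau 0.7.
#'
#' @param n_ms,n_ctrl,n_healthy_ref Cohort sizes.
#' @param n_analytes Number of panel analytes (at most 48, taken in the
#'   order of [cytokine_categories]).
#' @param clones_per_blood,clones_per_csf,clones_per_healthy Clones per
#'   repertoire (at most 8000).
#' @param blood_templates,csf_templates Total template counts distributed
#'   across a repertoire's clones.
#' @param ms_csf_template_fold Multiplier on CSF template totals in MS
#'   (emulates the higher intrathecal T-cell load).
#' @param zipf_exponent Positive exponent of the clone-size power law.
#' @param sharing_rate_ms,sharing_rate_ctrl Probability that a CSF clone is
#'   copied into the paired blood repertoire (counts re-drawn).
#' @param nonproductive_fraction Fraction of extra out-of-frame/stop rows
#'   added per sample.
#' @param public_fraction Fraction of each repertoire drawn from the shared
#'   public pool (the rest is private).
#' @param pool_size Size of the shared identity pool (split between a
#'   blood-side and a CSF-side half, so cross-compartment sharing arises
#'   only from the explicit sharing mechanism).
#' @param planted_fold_changes Named vector analyte -> MS/CTRL ratio,
#'   applied to the CSF panel.
#' @param correlation_blocks List of `list(analytes = <chr>, r = <num>)`
#'   blocks planted in the latent log-scale correlation matrix (disjoint;
#'   must be positive semi-definite).
#' @param planted_links Tibble `sequence`/`analyte`/`tau`: MS-predominant
#'   sequences inserted into every MS blood repertoire with counts linked
#'   to the analyte's blood level through a Gaussian copula.
#' @param n_ms_cluster_seqs,ms_cluster_occ_ms,ms_cluster_occ_healthy
#'   MS-enriched cluster sequences: how many, and their occurrence
#'   probability per MS blood / healthy sample. Each is also planted into
#'   two MS CSF samples so it qualifies as a PRS.
#' @param n_general_seqs,general_occ Background cluster sequences present
#'   at equal occurrence in both groups (also planted into two MS CSF
#'   samples each).
#' @param planted_trbv_shift Optional `list(gene =, fold =)` multiplying one
#'   TRBV gene's usage weight in MS samples.
#' @param noise_sdlog2 Log2-scale standard deviation of analyte noise.
#' @param base_log2_range Range of per-analyte baseline log2
#'   concentrations.
#' @param detection_limit Concentration below which a measurement is masked
#'   as not detected.
#' @param hla_prevalence_ms,hla_prevalence_ctrl HLA-DRB1*15:01 carriage
#'   probability among typed patients.
#' @param n_hla_typed_ms,n_hla_typed_ctrl Patients with known HLA typing.
#' @param n_ms_no_blood MS patients without a blood repertoire (their CSF
#'   is still profiled), mirroring missing EDTA samples.
#' @param seed Integer RNG seed (< 2^31 - 10).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_ms = 24L, n_ctrl = 9L, n_healthy_ref = 88L,
                          n_analytes = 48L,
                          clones_per_blood = 2000L, clones_per_csf = 400L,
                          clones_per_healthy = 1000L,
                          blood_templates = 20000L, csf_templates = 3000L,
                          ms_csf_template_fold = 2,
                          zipf_exponent = 1.1,
                          sharing_rate_ms = 0.005, sharing_rate_ctrl = 0.001,
                          nonproductive_fraction = 0.15,
                          public_fraction = 0.1, pool_size = 200000L,
                          planted_fold_changes = c("MIP-1a" = 2.57, "IP-10" = 1.91),
                          correlation_blocks = list(
                            list(analytes = c("G-CSF", "HGF", "PDGF-BB", "SCF"),
                                 r = 0.9)),
                          planted_links = default_planted_links(),
                          n_ms_cluster_seqs = 25L, ms_cluster_occ_ms = 0.20,
                          ms_cluster_occ_healthy = 0.04,
                          n_general_seqs = 25L, general_occ = 0.05,
                          planted_trbv_shift = NULL,
                          noise_sdlog2 = 0.4, base_log2_range = c(3, 8),
                          detection_limit = 2,
                          hla_prevalence_ms = 0.5, hla_prevalence_ctrl = 0.125,
                          n_hla_typed_ms = min(22L, n_ms),
                          n_hla_typed_ctrl = min(8L, n_ctrl),
                          n_ms_no_blood = if (n_ms >= 8L) 3L else 0L,
                          seed = 1L) {
  n_ms <- assert_count(n_ms, "n_ms", 1L)
  n_ctrl <- assert_count(n_ctrl, "n_ctrl", 1L)
  n_healthy_ref <- assert_count(n_healthy_ref, "n_healthy_ref", 0L)
  n_analytes <- assert_count(n_analytes, "n_analytes", 2L)
  if (n_analytes > nrow(cytokine_categories)) {
    abort(sprintf("`n_analytes` cannot exceed %d.", nrow(cytokine_categories)))
  }
  for (nm in c("clones_per_blood", "clones_per_csf", "clones_per_healthy")) {
    v <- get(nm)
    assert_count(v, nm, 1L)
    if (v > 8000L) abort(sprintf("`%s` cannot exceed 8000 (id-space allocation).", nm))
  }
  if (clones_per_csf > clones_per_blood) {
    warn("clones_per_csf > clones_per_blood: unusual, but allowed.")
  }
  if (!is.numeric(zipf_exponent) || zipf_exponent <= 0) {
    abort("`zipf_exponent` must be positive.")
  }
  assert_fraction(c(sharing_rate_ms, sharing_rate_ctrl), "sharing_rate")
  assert_fraction(nonproductive_fraction, "nonproductive_fraction")
  assert_fraction(public_fraction, "public_fraction")
  assert_fraction(c(ms_cluster_occ_ms, ms_cluster_occ_healthy, general_occ),
                  "occurrence probabilities")
  assert_fraction(c(hla_prevalence_ms, hla_prevalence_ctrl), "hla_prevalence")
  if (pool_size < 2L || pool_size > 900000L) {
    abort("`pool_size` must lie in [2, 900000].")
  }
  analytes <- head(cytokine_categories$analyte, n_analytes)
  if (length(planted_fold_changes)) {
    if (is.null(names(planted_fold_changes)) ||
        any(planted_fold_changes <= 0)) {
      abort("`planted_fold_changes` must be a named vector of positive ratios.")
    }
    bad <- setdiff(names(planted_fold_changes), analytes)
    if (length(bad)) abort(paste0("planted fold-change analytes not in the panel: ",
                                  paste(bad, collapse = ", ")))
  }
  seen <- character()
  for (i in seq_along(correlation_blocks)) {
    bl <- correlation_blocks[[i]]
    if (!is.list(bl) || is.null(bl$analytes) || is.null(bl$r)) {
      abort(sprintf("correlation block %d must be list(analytes =, r =).", i))
    }
    k <- length(bl$analytes)
    if (k < 2L) abort(sprintf("correlation block %d needs >= 2 analytes.", i))
    if (bl$r <= -1 || bl$r >= 1) abort(sprintf("correlation block %d: r must lie in (-1, 1).", i))
    if (bl$r < -1 / (k - 1)) {
      abort(sprintf(
        "correlation block %d (%s) is not positive semi-definite: r = %.3f < -1/(k-1) = %.3f.",
        i, paste(bl$analytes, collapse = ", "), bl$r, -1 / (k - 1)))
    }
    bad <- setdiff(bl$analytes, analytes)
    if (length(bad)) abort(sprintf("correlation block %d names unknown analytes: %s",
                                   i, paste(bad, collapse = ", ")))
    if (length(intersect(bl$analytes, seen))) {
      abort(sprintf("correlation block %d overlaps an earlier block.", i))
    }
    seen <- c(seen, bl$analytes)
  }
  planted_links <- if (is.null(planted_links)) {
    tibble(sequence = character(), analyte = character(), tau = double())
  } else tibble::as_tibble(planted_links)
  if (nrow(planted_links)) {
    if (!all(c("sequence", "analyte", "tau") %in% names(planted_links))) {
      abort("`planted_links` needs columns sequence, analyte, tau.")
    }
    if (any(abs(planted_links$tau) > 1)) abort("link tau must lie in [-1, 1].")
    bad <- setdiff(planted_links$analyte, analytes)
    if (length(bad)) abort(paste0("planted link analytes not in the panel: ",
                                  paste(bad, collapse = ", ")))
  }
  if (!is.null(planted_trbv_shift)) {
    if (!all(c("gene", "fold") %in% names(planted_trbv_shift)) ||
        !planted_trbv_shift$gene %in% trbv_gene_table$gene ||
        planted_trbv_shift$fold <= 0) {
      abort("`planted_trbv_shift` must be list(gene = <TRBV gene>, fold = positive).")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed > 2^31 - 10) {
    abort("`seed` must be a single integer below 2^31 - 10.")
  }
  seed <- assert_count(seed, "seed", 0L)
  if (n_hla_typed_ms > n_ms || n_hla_typed_ctrl > n_ctrl) {
    abort("typed patient counts cannot exceed group sizes.")
  }
  if (n_ms_no_blood >= n_ms) abort("`n_ms_no_blood` must leave at least one MS blood sample.")
  structure(list(
    n_ms = n_ms, n_ctrl = n_ctrl, n_healthy_ref = n_healthy_ref,
    n_analytes = n_analytes, analytes = analytes,
    clones_per_blood = as.integer(clones_per_blood),
    clones_per_csf = as.integer(clones_per_csf),
    clones_per_healthy = as.integer(clones_per_healthy),
    blood_templates = as.integer(blood_templates),
    csf_templates = as.integer(csf_templates),
    ms_csf_template_fold = ms_csf_template_fold,
    zipf_exponent = zipf_exponent,
    sharing_rate_ms = sharing_rate_ms, sharing_rate_ctrl = sharing_rate_ctrl,
    nonproductive_fraction = nonproductive_fraction,
    public_fraction = public_fraction, pool_size = as.integer(pool_size),
    planted_fold_changes = planted_fold_changes,
    correlation_blocks = correlation_blocks,
    planted_links = planted_links,
    n_ms_cluster_seqs = as.integer(n_ms_cluster_seqs),
    ms_cluster_occ_ms = ms_cluster_occ_ms,
    ms_cluster_occ_healthy = ms_cluster_occ_healthy,
    n_general_seqs = as.integer(n_general_seqs), general_occ = general_occ,
    planted_trbv_shift = planted_trbv_shift,
    noise_sdlog2 = noise_sdlog2, base_log2_range = base_log2_range,
    detection_limit = detection_limit,
    hla_prevalence_ms = hla_prevalence_ms,
    hla_prevalence_ctrl = hla_prevalence_ctrl,
    n_hla_typed_ms = as.integer(n_hla_typed_ms),
    n_hla_typed_ctrl = as.integer(n_hla_typed_ctrl),
    n_ms_no_blood = as.integer(n_ms_no_blood),
    seed = seed
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config> %d MS + %d CTRL (+%d healthy ref), %d analytes, seed %d\n",
    "  clones: blood %d / CSF %d; sharing %.3f (MS) vs %.3f (CTRL); %d planted links\n"),
    x$n_ms, x$n_ctrl, x$n_healthy_ref, x$n_analytes, x$seed,
    x$clones_per_blood, x$clones_per_csf,
    x$sharing_rate_ms, x$sharing_rate_ctrl, nrow(x$planted_links)))
  invisible(x)
}
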