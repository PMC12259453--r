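# Synthetic cohort generation: metadata, cytokine panels with planted group
# fold changes and correlation blocks, and paired repertoires with power-law
# clone sizes, controlled CSF-to-blood sharing, planted cluster sequences
# and copula-linked sequence-cytokine associations. Everything is seeded
# (Mersenne-Twister substreams derived from config$seed) so identical
# configurations reproduce byte-identical cohorts.

#' Generate synthetic cohort metadata
#'
#' Patients, group labels, HLA-DRB1*15:01 flags (known only for the typed
#' subset), age/sex/EDSS covariates, compartment availability, and the
#' derived sample table (`sample_id = <patient>_<compartment>`).
#'
#' @param config A [cohort_config()].
#' @return List with `patients` and `samples` tibbles.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ids_ms <- sprintf("MS%02d", seq_len(config$n_ms))
  ids_ct <- sprintf("CT%02d", seq_len(config$n_ctrl))
  ids_hc <- if (config$n_healthy_ref > 0) sprintf("HC%02d", seq_len(config$n_healthy_ref)) else character()
  n_all <- length(ids_ms) + length(ids_ct) + length(ids_hc)
  typed_ms <- sample(ids_ms, config$n_hla_typed_ms)
  typed_ct <- sample(ids_ct, config$n_hla_typed_ctrl)
  hla <- rep(NA, n_all)
  patients <- tibble(
    patient_id = c(ids_ms, ids_ct, ids_hc),
    group = c(rep("MS", length(ids_ms)), rep("CTRL", length(ids_ct)),
              rep("HEALTHY_REF", length(ids_hc))),
    age = round(stats::rnorm(n_all, 36, 9)),
    sex = sample(c("F", "M"), n_all, replace = TRUE, prob = c(0.65, 0.35)),
    edss = NA_real_,
    hla_drb1_1501 = hla,
    has_blood = TRUE,
    has_csf = FALSE
  )
  patients$age <- pmin(pmax(patients$age, 18), 65)
  is_ms <- patients$group == "MS"
  is_ct <- patients$group == "CTRL"
  patients$edss[is_ms] <- sample(c(0, 1, 1, 1.5, 2, 2.5), sum(is_ms), replace = TRUE)
  patients$hla_drb1_1501[patients$patient_id %in% typed_ms] <-
    stats::rbinom(length(typed_ms), 1L, config$hla_prevalence_ms) == 1L
  patients$hla_drb1_1501[patients$patient_id %in% typed_ct] <-
    stats::rbinom(length(typed_ct), 1L, config$hla_prevalence_ctrl) == 1L
  patients$has_csf[is_ms | is_ct] <- TRUE
  if (config$n_ms_no_blood > 0L) {
    no_blood <- sample(ids_ms, config$n_ms_no_blood)
    patients$has_blood[patients$patient_id %in% no_blood] <- FALSE
  }
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
  list(patients = patients, samples = samples)
}

#' Generate synthetic cytokine panels
#'
#' Concentrations are log-normal: a per-analyte baseline plus correlated
#' Gaussian noise on the log2 scale (correlation blocks planted in the
#' latent covariance), exponentiated, with the planted MS/CTRL fold
#' changes applied multiplicatively to the CSF panel. Values below the
#' detection limit are masked as not detected.
#'
#' @param config A [cohort_config()].
#' @param metadata Output of [generate_metadata()]; regenerated when
#'   omitted.
#' @return List with `csf` and `blood` [cytokine_panel] objects and
#'   `ground_truth` (planted structure plus realized group ratios and the
#'   latent blood matrix used for copula links).
#' @export
generate_cytokines <- function(config, metadata = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  metadata <- metadata %||% generate_metadata(config)
  set.seed(config$seed + 1L)
  analytes <- config$analytes
  K <- length(analytes)
  pats <- metadata$patients |>
    dplyr::filter(.data$group %in% c("MS", "CTRL"))
  n <- nrow(pats)
  is_ms <- pats$group == "MS"
  base <- stats::runif(K, config$base_log2_range[1], config$base_log2_range[2])
  names(base) <- analytes
  sigma <- diag(K)
  dimnames(sigma) <- list(analytes, analytes)
  for (bl in config$correlation_blocks) {
    ix <- match(bl$analytes, analytes)
    sigma[ix, ix] <- bl$r
    diag(sigma)[ix] <- 1
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    abort("the combined correlation-block specification is not positive definite.")
  })
  fc <- setNames(rep(1, K), analytes)
  fc[names(config$planted_fold_changes)] <- config$planted_fold_changes
  make_panel <- function(compartment) {
    z <- matrix(stats::rnorm(n * K), n, K) %*% ch
    shift <- if (compartment == "CSF") log2(fc) else rep(0, K)
    offs <- if (compartment == "blood") 1 else 0
    log2conc <- sweep(z * config$noise_sdlog2, 2L, base + offs, "+") +
      outer(as.numeric(is_ms), shift)
    conc <- 2^log2conc
    dimnames(conc) <- list(pats$patient_id, analytes)
    raw <- conc
    conc[conc < config$detection_limit] <- NA
    list(panel = cytokine_panel(conc,
                                categories = cytokine_categories[
                                  cytokine_categories$analyte %in% analytes, ]),
         raw = raw, latent = z)
  }
  csf <- make_panel("CSF")
  blood <- make_panel("blood")
  realized <- vapply(names(config$planted_fold_changes), function(a) {
    mean(csf$raw[is_ms, a]) / mean(csf$raw[!is_ms, a])
  }, 0)
  latent_blood <- blood$latent
  dimnames(latent_blood) <- list(pats$patient_id, analytes)
  list(
    csf = csf$panel, blood = blood$panel,
    ground_truth = list(
      planted_fold_changes = config$planted_fold_changes,
      realized_csf_ratios = realized,
      correlation_blocks = config$correlation_blocks,
      noise_sdlog2 = config$noise_sdlog2,
      latent_blood = latent_blood
    )
  )
}

# multinomial clone counts over a Zipf profile; +1 so every clone is
# observed (sharing and publicity stay exactly as planted)
zipf_counts <- function(n_clones, total, exponent) {
  p <- (seq_len(n_clones))^(-exponent)
  as.vector(stats::rmultinom(1L, max(total - n_clones, 0L), p / sum(p))) + 1L
}

#' Generate synthetic rearrangement tables
#'
#' Per patient, one blood and one CSF repertoire (healthy reference donors:
#' blood only). Clone counts follow a Zipf law (multinomial draw over a
#' power-law profile); identities mix a shared public pool with private
#' clones; a `sharing_rate` fraction of CSF clones is copied into the
#' paired blood repertoire with counts re-drawn. Planted MS-cluster /
#' general sequences and copula-linked MS-predominant sequences are
#' inserted on top, and a fraction of non-productive rows is added.
#'
#' @param config A [cohort_config()].
#' @param metadata Output of [generate_metadata()]; regenerated when
#'   omitted.
#' @param cytokines Output of [generate_cytokines()]; required (and
#'   regenerated when omitted) if `planted_links` is non-empty.
#' @return List with `rearrangements` (one long tibble over all samples)
#'   and `ground_truth` (planted sequences, realized per-patient sharing
#'   fractions, planted TRBV shift).
#' @export
generate_repertoires <- function(config, metadata = NULL, cytokines = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  metadata <- metadata %||% generate_metadata(config)
  if (nrow(config$planted_links) && is.null(cytokines)) {
    cytokines <- generate_cytokines(config, metadata)
  }
  set.seed(config$seed + 2L)
  samples <- metadata$samples
  pool_half <- config$pool_size %/% 2L
  blood_pool <- seq_len(pool_half)
  csf_pool <- pool_half + seq_len(config$pool_size - pool_half)

  n_samp <- nrow(samples)
  alloc <- max(10000L, as.integer(ceiling(1.5 * max(config$clones_per_blood,
                                                    config$clones_per_csf,
                                                    config$clones_per_healthy))))
  if (private_id_base + n_samp * alloc >= link_id_base) {
    abort("cohort too large for the private id space.")
  }
  sample_index <- setNames(seq_len(n_samp), samples$sample_id)

  draw_ids <- function(sample_id, n, pool, extra_shared = integer()) {
    k_pub <- round(config$public_fraction * n)
    k_shared <- length(extra_shared)
    k_priv <- max(n - k_pub - k_shared, 0L)
    pub <- if (k_pub > 0L) sample(pool, k_pub) else integer()
    priv <- if (k_priv > 0L) private_id_base +
      (sample_index[[sample_id]] - 1L) * alloc + seq_len(k_priv) else integer()
    c(extra_shared, pub, priv)
  }

  csf_ids <- list()   # per patient, for sharing
  parts <- vector("list", n_samp)
  realized_sharing <- list()

  # CSF first so the shared clones are known when blood is built
  ord <- order(samples$compartment != "CSF")
  for (si in ord) {
    sm <- samples[si, ]
    is_csf <- sm$compartment == "CSF"
    if (is_csf) {
      n_cl <- config$clones_per_csf
      total <- config$csf_templates *
        (if (sm$group == "MS") config$ms_csf_template_fold else 1)
      ids <- draw_ids(sm$sample_id, n_cl, csf_pool)
      csf_ids[[sm$patient_id]] <- ids
    } else {
      n_cl <- if (sm$group == "HEALTHY_REF") config$clones_per_healthy else
        config$clones_per_blood
      total <- config$blood_templates
      shared <- integer()
      if (sm$group %in% c("MS", "CTRL") && !is.null(csf_ids[[sm$patient_id]])) {
        rate <- if (sm$group == "MS") config$sharing_rate_ms else config$sharing_rate_ctrl
        src <- csf_ids[[sm$patient_id]]
        shared <- src[stats::runif(length(src)) < rate]
        realized_sharing[[sm$patient_id]] <- tibble(
          patient_id = sm$patient_id, group = sm$group,
          n_csf_clones = length(src), n_shared = length(shared),
          realized_rate = length(shared) / length(src)
        )
      }
      ids <- draw_ids(sm$sample_id, n_cl, blood_pool, extra_shared = shared)
    }
    counts <- zipf_counts(length(ids), round(total), config$zipf_exponent)
    parts[[si]] <- tibble(sample_id = sm$sample_id,
                          id = ids[sample.int(length(ids))],
                          templates = counts)
  }
  long <- dplyr::bind_rows(parts)

  # planted cluster sequences: presence sampled per sample; each also seeded
  # into two MS CSF samples, preferentially ones whose blood lacks it so the
  # planted sharing rates stay untouched
  ms_blood <- samples$sample_id[samples$group == "MS" & samples$compartment == "blood"]
  ms_csf <- samples$sample_id[samples$group == "MS" & samples$compartment == "CSF"]
  ct_blood <- samples$sample_id[samples$group == "CTRL" & samples$compartment == "blood"]
  hc_blood <- samples$sample_id[samples$group == "HEALTHY_REF"]
  plant_rows <- list()
  plant_cluster <- function(id_base, n_seq, occ_ms, occ_hc) {
    if (n_seq <= 0L) return(tibble(id = integer(), sequence = character()))
    ids <- id_base + seq_len(n_seq)
    aa <- encode_cdr3(ids)$aa
    for (j in seq_len(n_seq)) {
      in_blood <- ms_blood[stats::runif(length(ms_blood)) < occ_ms]
      in_ct <- ct_blood[stats::runif(length(ct_blood)) < occ_hc]
      in_hc <- hc_blood[stats::runif(length(hc_blood)) < occ_hc]
      blood_pat <- sub("_blood$", "", in_blood)
      pref <- ms_csf[!sub("_CSF$", "", ms_csf) %in% blood_pat]
      if (length(pref) < 2L) pref <- ms_csf
      in_csf <- sample(pref, min(2L, length(pref)))
      hit <- c(in_blood, in_ct, in_hc, in_csf)
      if (length(hit)) {
        plant_rows[[length(plant_rows) + 1L]] <<- tibble(
          sample_id = hit, id = ids[j],
          templates = stats::rpois(length(hit), 2L) + 2L
        )
      }
    }
    tibble(id = ids, sequence = aa)
  }
  gt_ms_cluster <- plant_cluster(ms_cluster_id_base, config$n_ms_cluster_seqs,
                                 config$ms_cluster_occ_ms, config$ms_cluster_occ_healthy)
  gt_general <- plant_cluster(general_id_base, config$n_general_seqs,
                              config$general_occ, config$general_occ)

  # planted sequence-cytokine links: present in every MS blood repertoire,
  # counts tied to the analyte's latent blood level by a Gaussian copula
  links <- config$planted_links
  if (nrow(links)) {
    latent <- cytokines$ground_truth$latent_blood
    ms_blood_pat <- sub("_blood$", "", ms_blood)
    for (j in seq_len(nrow(links))) {
      rho <- sin(pi * links$tau[j] / 2)
      zc <- latent[ms_blood_pat, links$analyte[j]]
      zs <- rho * zc + sqrt(max(1 - rho^2, 0)) * stats::rnorm(length(zc))
      cnt <- pmax(1L, as.integer(round(2^(4 + 1.2 * zs))))
      plant_rows[[length(plant_rows) + 1L]] <- tibble(
        sample_id = ms_blood, id = link_id_base + j, templates = cnt
      )
    }
  }
  if (length(plant_rows)) {
    long <- dplyr::bind_rows(long, dplyr::bind_rows(plant_rows))
  }
  long$frame <- "In"

  # non-productive rows drawn per sample from a reserved private sub-range
  npf <- config$nonproductive_fraction
  if (npf > 0) {
    per_sample <- long |> dplyr::count(.data$sample_id)
    np <- per_sample |>
      dplyr::mutate(n_np = round(npf * .data$n)) |>
      dplyr::filter(.data$n_np > 0L)
    if (nrow(np)) {
      np_rows <- lapply(seq_len(nrow(np)), function(i) {
        sid <- np$sample_id[i]; k <- np$n_np[i]
        tibble(sample_id = sid,
               id = private_id_base + (sample_index[[sid]] - 1L) * alloc +
                 alloc - seq_len(k),
               templates = stats::rpois(k, 2L) + 1L,
               frame = sample(c("Out", "Stop"), k, replace = TRUE))
      })
      long <- dplyr::bind_rows(long, dplyr::bind_rows(np_rows))
    }
  }

  # gene segment calls; one TRBV gene's weight optionally shifted in MS
  long <- dplyr::left_join(long, samples, by = "sample_id")
  n_rows <- nrow(long)
  base_w <- trbv_gene_table$weight
  v_gene <- character(n_rows)
  is_ms_row <- long$group == "MS"
  if (!is.null(config$planted_trbv_shift)) {
    w_ms <- base_w
    w_ms[trbv_gene_table$gene == config$planted_trbv_shift$gene] <-
      w_ms[trbv_gene_table$gene == config$planted_trbv_shift$gene] *
      config$planted_trbv_shift$fold
    w_ms <- w_ms / sum(w_ms)
  } else {
    w_ms <- base_w
  }
  v_gene[!is_ms_row] <- sample(trbv_gene_table$gene, sum(!is_ms_row),
                               replace = TRUE, prob = base_w)
  v_gene[is_ms_row] <- sample(trbv_gene_table$gene, sum(is_ms_row),
                              replace = TRUE, prob = w_ms)
  enc <- encode_cdr3(long$id)
  rearrangements <- tibble(
    sample_id = long$sample_id,
    patient_id = long$patient_id,
    compartment = long$compartment,
    group = long$group,
    cdr3_nt = enc$nt,
    cdr3_aa = enc$aa,
    v_gene = v_gene,
    d_gene = sample(trbd_genes, n_rows, replace = TRUE),
    j_gene = sample(trbj_genes, n_rows, replace = TRUE),
    templates = long$templates,
    frame_type = long$frame,
    productive = long$frame == "In"
  ) |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$templates), .data$cdr3_aa)

  list(
    rearrangements = rearrangements,
    ground_truth = list(
      sharing = dplyr::bind_rows(realized_sharing),
      planted_links = links,
      ms_cluster_sequences = gt_ms_cluster$sequence,
      general_sequences = gt_general$sequence,
      planted_trbv_shift = config$planted_trbv_shift,
      zipf_exponent = config$zipf_exponent
    )
  )
}

#' Simulate a full synthetic study
#'
#' Metadata, cytokine panels and repertoires in one deterministic call.
#'
#' @param config A [cohort_config()].
#' @return A `tcr_cohort`: list with `config`, `metadata`, `cytokines`
#'   (`csf`, `blood` panels), `rearrangements` and `ground_truth`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  metadata <- generate_metadata(config)
  cyt <- generate_cytokines(config, metadata)
  rep <- generate_repertoires(config, metadata, cyt)
  structure(list(
    config = config,
    metadata = metadata,
    cytokines = list(csf = cyt$csf, blood = cyt$blood),
    rearrangements = rep$rearrangements,
    ground_truth = c(cyt$ground_truth[setdiff(names(cyt$ground_truth), "latent_blood")],
                     rep$ground_truth)
  ), class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("<tcr_cohort> %d samples, %d rearrangement rows, %d analytes\n",
              nrow(x$metadata$samples), nrow(x$rearrangements),
              ncol(x$cytokines$csf$values)))
  invisible(x)
}
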