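# The synthetic cohort generator: determinism, table counts, clone-size
# law, planted structure plumbing, configuration validation and
# serialization round trips.

test_that("identical configurations reproduce byte-identical cohorts", {
  cfg <- small_cohort_config(seed = 90L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(small_cohort_config(seed = 90L))
  expect_identical(c1$rearrangements, c2$rearrangements)
  expect_identical(c1$cytokines$csf$values, c2$cytokines$csf$values)
  expect_identical(c1$metadata$patients, c2$metadata$patients)
  c3 <- simulate_cohort(small_cohort_config(seed = 91L))
  expect_false(identical(c1$rearrangements, c3$rearrangements))
})

test_that("the expected number of rearrangement tables is emitted", {
  cfg <- cohort_config(n_ms = 4L, n_ctrl = 2L, n_healthy_ref = 3L,
                       n_ms_no_blood = 0L,
                       clones_per_blood = 60L, clones_per_csf = 30L,
                       clones_per_healthy = 40L,
                       blood_templates = 600L, csf_templates = 300L,
                       planted_links = NULL, seed = 92L)
  rep_ <- generate_repertoires(cfg)
  # paired CSF + blood for MS and CTRL, blood only for the reference cohort
  expect_equal(dplyr::n_distinct(rep_$rearrangements$sample_id),
               4L * 2L + 2L * 2L + 3L)
  by_comp <- rep_$rearrangements |>
    dplyr::distinct(sample_id, compartment, group) |>
    dplyr::count(group, compartment)
  expect_equal(by_comp$n[by_comp$group == "HEALTHY_REF"], 3L)
  expect_false("CSF" %in% by_comp$compartment[by_comp$group == "HEALTHY_REF"])
})

test_that("zero sharing and no planted links yield zero shared clones", {
  cfg <- small_cohort_config(seed = 93L, sharing_rate_ms = 0,
                             sharing_rate_ctrl = 0, planted_links = NULL,
                             n_ms_cluster_seqs = 0L, n_general_seqs = 0L)
  co <- simulate_cohort(cfg)
  sh <- sharing_summary(clone_ledger(co$rearrangements))
  expect_true(all(sh$patients$n_shared == 0L))
})

test_that("realized sharing tracks the configured rates", {
  cfg <- cohort_config(seed = 94L, n_healthy_ref = 0L,
                       clones_per_csf = 2000L, clones_per_blood = 4000L,
                       sharing_rate_ms = 0.05, sharing_rate_ctrl = 0.01,
                       planted_links = NULL, n_ms_cluster_seqs = 0L,
                       n_general_seqs = 0L)
  co <- simulate_cohort(cfg)
  sh <- sharing_summary(clone_ledger(co$rearrangements))
  ms <- mean(sh$patients$pct_shared_of_csf[sh$patients$group == "MS"])
  ct <- mean(sh$patients$pct_shared_of_csf[sh$patients$group == "CTRL"])
  expect_lt(abs(ms - 5), 1)
  expect_lt(abs(ct - 1), 0.6)
  gt <- co$ground_truth$sharing
  expect_true(all(gt$patient_id %in% co$metadata$patients$patient_id))
})

test_that("clone sizes follow the configured power law", {
  cfg <- cohort_config(seed = 95L, n_ms = 1L, n_ctrl = 1L, n_healthy_ref = 0L,
                       clones_per_blood = 6000L, clones_per_csf = 50L,
                       blood_templates = 2000000L, csf_templates = 500L,
                       zipf_exponent = 1.1, planted_links = NULL,
                       n_ms_cluster_seqs = 0L, n_general_seqs = 0L,
                       nonproductive_fraction = 0, n_ms_no_blood = 0L,
                       n_hla_typed_ms = 1L, n_hla_typed_ctrl = 1L)
  rep_ <- generate_repertoires(cfg)
  counts <- rep_$rearrangements |>
    dplyr::filter(sample_id == "MS01_blood") |>
    dplyr::pull(templates) |>
    sort(decreasing = TRUE)
  keep <- counts >= 10  # above the discreteness floor
  fit <- lm(log(counts[keep]) ~ log(seq_along(counts)[keep]))
  expect_lt(abs(unname(coef(fit)[2]) + 1.1), 0.3)
})

test_that("planted ground truth names entities that exist in the cohort", {
  co <- simulate_cohort(small_cohort_config(seed = 96L))
  gt <- co$ground_truth
  aa <- unique(co$rearrangements$cdr3_aa)
  expect_true(all(gt$planted_links$sequence %in% aa))
  expect_true(all(gt$ms_cluster_sequences %in% aa))
  expect_true(all(gt$general_sequences %in% aa))
  expect_true(all(names(gt$planted_fold_changes) %in%
                    colnames(co$cytokines$csf$values)))
  # every planted link sequence sits in at least 5 MS blood repertoires
  occ <- co$rearrangements |>
    dplyr::filter(cdr3_aa %in% gt$planted_links$sequence,
                  group == "MS", compartment == "blood") |>
    dplyr::count(cdr3_aa)
  expect_true(all(occ$n >= 5L))
})

test_that("planted CSF fold changes shift the generated concentrations", {
  cfg <- cohort_config(seed = 97L, n_healthy_ref = 0L, planted_links = NULL)
  cyt <- generate_cytokines(cfg)
  expect_equal(unname(cyt$ground_truth$planted_fold_changes["MIP-1a"]), 2.57)
  ratios <- cyt$ground_truth$realized_csf_ratios
  expect_lt(abs(ratios[["MIP-1a"]] / 2.57 - 1), 0.6)
  expect_lt(abs(ratios[["IP-10"]] / 1.91 - 1), 0.6)
})

test_that("detection limits mask low concentrations as not detected", {
  cfg <- cohort_config(seed = 98L, detection_limit = 50,
                       base_log2_range = c(3, 6), planted_links = NULL)
  cyt <- generate_cytokines(cfg)
  v <- cyt$blood$values
  expect_true(anyNA(v))
  expect_true(all(v >= 50, na.rm = TRUE))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(cohort_config(zipf_exponent = -1), "positive")
  expect_error(cohort_config(sharing_rate_ms = 1.5), "fraction")
  expect_error(cohort_config(correlation_blocks = list(
    list(analytes = c("CTACK", "Eotaxin", "IL-8"), r = -0.9))),
    "not positive semi-definite")
  expect_error(cohort_config(correlation_blocks = list(
    list(analytes = c("CTACK", "NOPE"), r = 0.5))), "unknown analytes")
  expect_error(cohort_config(planted_fold_changes = c(NOPE = 2)), "not in the panel")
  expect_error(cohort_config(clones_per_blood = 0), "integer")
  expect_error(cohort_config(seed = 2^31), "below 2\\^31")
  expect_warning(cohort_config(clones_per_csf = 500, clones_per_blood = 400),
                 "unusual")
})

test_that("write_cohort manifests match the in-memory tables and round-trip", {
  co <- simulate_cohort(small_cohort_config(seed = 99L))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  per_sample <- co$rearrangements |> dplyr::count(sample_id)
  rep_rows <- manifest[startsWith(manifest$file, "repertoires/"), ]
  expect_equal(nrow(rep_rows), nrow(per_sample))
  expect_equal(sum(rep_rows$n_rows), sum(per_sample$n))
  back <- read_cohort(dir)
  expect_equal(nrow(back$rearrangements), nrow(co$rearrangements))
  expect_equal(back$cytokines$csf$values, co$cytokines$csf$values)
  expect_equal(back$metadata$patients$patient_id, co$metadata$patients$patient_id)
  key <- function(rr) dplyr::arrange(rr[, c("sample_id", "cdr3_aa", "cdr3_nt",
                                            "templates", "frame_type")],
                                     sample_id, cdr3_aa, cdr3_nt, templates)
  expect_equal(as.data.frame(key(back$rearrangements)),
               as.data.frame(key(co$rearrangements)))
})

test_that("an empty cohort writes a warning and only metadata", {
  co <- simulate_cohort(small_cohort_config(seed = 100L))
  co$rearrangements <- NULL
  co$cytokines <- list()
  dir <- withr::local_tempdir()
  expect_warning(manifest <- write_cohort(co, dir), "empty cohort")
  expect_equal(manifest$file, "metadata.csv")
})
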