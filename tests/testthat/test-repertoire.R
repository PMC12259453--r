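# Clone ledger, clone taxonomy, sharing, clonality, sample statistics and
# TRBV usage.

test_that("clone counts of identical CDR3.aa are summed across clonotypes", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = "MS01", compartment = "CSF",
    cdr3_aa = c("CASSA", "CASSA", "CASSB"),
    templates = c(3L, 2L, 4L)
  ))
  rr$cdr3_nt[2] <- paste0(rr$cdr3_nt[2], "AAA")  # distinct clonotype, same aa
  led <- clone_ledger(rr)
  expect_equal(nrow(led$clones), 2L)
  expect_equal(led$clones$templates[led$clones$cdr3_aa == "CASSA"], 5L)
  expect_equal(led$samples$productive_templates, 9L)
  expect_equal(led$samples$n_unique_cdr3aa, 2L)
})

test_that("non-productive rows are excluded by default but counted in totals", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = "MS01", compartment = "CSF",
    cdr3_aa = c("CASSA", "CASSB"),
    templates = c(3L, 7L),
    productive = c(TRUE, FALSE)
  ))
  led <- clone_ledger(rr)
  expect_equal(nrow(led$clones), 1L)
  expect_equal(led$samples$total_templates, 10L)
  expect_equal(led$samples$productive_templates, 3L)
  led_all <- clone_ledger(rr, productive_only = FALSE)
  expect_equal(nrow(led_all$clones), 2L)
})

test_that("duplicate (patient, compartment) samples are rejected", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = "MS01", compartment = "CSF", cdr3_aa = "CASSA", templates = 1L))
  rr2 <- rr
  rr2$sample_id <- "other_id"
  expect_error(clone_ledger(dplyr::bind_rows(rr, rr2)), "duplicate")
})

test_that("ledger totals conserve the productive template sums of the input", {
  co <- simulate_cohort(small_cohort_config(seed = 61L))
  led <- clone_ledger(co$rearrangements)
  input <- co$rearrangements |>
    dplyr::filter(productive) |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(templates))
  by_clone <- led$clones |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(total = sum(templates))
  merged <- dplyr::left_join(input, by_clone, by = "sample_id")
  expect_equal(merged$total.x, merged$total.y)
  expect_equal(sort(led$samples$productive_templates),
               sort(input$total))
})

test_that("classify_clones implements the unique/shared x private/public taxonomy", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = c("P1", "P1", "P1", "P1", "P2"),
    compartment = c("CSF", "CSF", "blood", "blood", "blood"),
    cdr3_aa = c("X", "Y", "Y", "Z", "Z"),
    templates = 2L
  ))
  cl <- classify_clones(clone_ledger(rr))
  get <- function(aa, pat) cl[cl$cdr3_aa == aa & cl$patient_id == pat, ]
  expect_equal(get("Y", "P1")$sharing, "shared")
  expect_equal(get("X", "P1")$sharing, "unique")
  expect_equal(get("Z", "P1")$sharing, "unique")
  expect_false(get("X", "P1")$public)
  expect_true(get("Z", "P1")$public)   # found in P1 and P2
  expect_true(get("Z", "P2")$public)
  # same clone in CSF of two patients: unique in each, public overall
  rr2 <- toy_rearrangements(tibble::tibble(
    patient_id = c("P1", "P2"), compartment = "CSF", cdr3_aa = "W", templates = 1L))
  cl2 <- classify_clones(clone_ledger(rr2))
  expect_equal(cl2$sharing, c("unique", "unique"))
  expect_true(all(cl2$public))
})

test_that("sharing percentages use distinct clones and the stated denominators", {
  blood_aa <- c(sprintf("B%03d", 1:199), "SHARED")
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = "MS01",
    compartment = c(rep("blood", 200), rep("CSF", 10)),
    cdr3_aa = c(blood_aa, "SHARED", sprintf("C%03d", 1:9)),
    templates = 2L
  ))
  sh <- sharing_summary(clone_ledger(rr))
  expect_equal(sh$patients$pct_shared_of_blood, 0.5)  # 1 of 200
  expect_equal(sh$patients$pct_shared_of_csf, 10)     # 1 of 10
  # same intersection on both axes
  with(sh$patients, expect_equal(pct_shared_of_blood * n_blood,
                                 pct_shared_of_csf * n_csf))
})

test_that("patients without both compartments are excluded and recorded", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    compartment = c("blood", "CSF", "blood"),
    cdr3_aa = c("A", "A", "B"), templates = 1L
  ))
  sh <- sharing_summary(clone_ledger(rr))
  expect_equal(sh$patients$patient_id, "P1")
  expect_equal(sh$excluded$patient_id, "P2")
  expect_equal(sh$patients$pct_shared_of_blood, 100)
})

test_that("zero overlap gives zero percent in both directions", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = "P1", compartment = c("blood", "CSF"),
    cdr3_aa = c("A", "B"), templates = 1L
  ))
  sh <- sharing_summary(clone_ledger(rr))
  expect_equal(sh$patients$pct_shared_of_blood, 0)
  expect_equal(sh$patients$pct_shared_of_csf, 0)
})

test_that("simpson clonality has its closed-form values and monotonicity", {
  expect_equal(simpson_clonality(10), 1)
  expect_equal(simpson_clonality(rep(3, 4)), 0.5)        # sqrt(4 * (1/4)^2)
  expect_equal(simpson_clonality(c(2, 1, 1)), sqrt(0.375), tolerance = 1e-12)
  expect_equal(simpson_clonality(rep(1, 16)), 1 / 4)     # 1/sqrt(N)
  expect_error(simpson_clonality(c(0, 0)), "positive")
  # splitting a clone into two equal halves reduces clonality
  expect_lt(simpson_clonality(c(4, 4, 2, 2)), simpson_clonality(c(8, 2, 2)))
  expect_equal(simpson_clonality(10, definition = "normalized_entropy"), 1)
  expect_equal(simpson_clonality(rep(2, 5), definition = "normalized_entropy"), 0)
})

test_that("sample_statistics computes totals, max frequency and Welch tests", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = c("P1", "P2", "P2"),
    compartment = "CSF",
    cdr3_aa = c("A", "A", "B"),
    templates = c(10L, 6L, 2L)
  ))
  st <- sample_statistics(clone_ledger(rr))
  p1 <- st$samples[st$samples$patient_id == "P1", ]
  expect_equal(p1$max_clone_freq_pct, 100)
  expect_equal(p1$clonality, 1)
  p2 <- st$samples[st$samples$patient_id == "P2", ]
  expect_equal(p2$max_clone_freq_pct, 75)
  expect_equal(st$samples$total_templates, c(10L, 8L))
})

test_that("sample_statistics Welch tests equal the textbook formula", {
  spec <- tibble::tibble(
    patient_id = rep(c("M1", "M2", "M3", "C1", "C2", "C3"), each = 1),
    group = rep(c("MS", "CTRL"), each = 3),
    compartment = "CSF",
    cdr3_aa = "A",
    templates = c(10L, 14L, 12L, 5L, 6L, 4L)
  )
  st <- sample_statistics(toy_ledger(spec))
  row <- st$tests[st$tests$statistic_name == "total_templates", ]
  o <- welch_oracle(c(10, 14, 12), c(5, 6, 4))
  expect_equal(row$statistic, o$t, tolerance = 1e-10)
  expect_equal(row$df, o$df, tolerance = 1e-10)
  expect_equal(row$p_value, o$p, tolerance = 1e-10)
})

test_that("TRBV proportions sum to one per sample and degenerate cases work", {
  rr <- toy_rearrangements(tibble::tibble(
    patient_id = c("P1", "P1", "P2"),
    compartment = "blood",
    group = c("MS", "MS", "CTRL"),
    cdr3_aa = c("A", "B", "C"),
    templates = c(6L, 2L, 5L),
    v_gene = c("TRBV28-1", "TRBV6-5", "TRBV28-1")
  ))
  u <- trbv_usage(rr)
  sums <- u$proportions |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(proportion))
  expect_equal(sums$s, rep(1, 2), tolerance = 1e-12)
  expect_equal(u$proportions$proportion[u$proportions$patient_id == "P2"], 1)
})

test_that("a planted TRBV usage shift is recovered as the top significant gene", {
  hits <- 0L
  nrep <- 12L
  for (r in seq_len(nrep)) {
    # near-uniform clone sizes: gene usage measured over distinct
    # rearrangements rather than being dominated by a few large clones
    cfg <- cohort_config(
      seed = 700L + r, n_healthy_ref = 0L,
      clones_per_blood = 2000L, blood_templates = 2000L,
      clones_per_csf = 400L, csf_templates = 400L,
      planted_trbv_shift = list(gene = "TRBV19-1", fold = 3),
      planted_links = NULL, n_ms_cluster_seqs = 0L, n_general_seqs = 0L)
    rep_ <- generate_repertoires(cfg)
    u <- trbv_usage(rep_$rearrangements)
    tb <- u$tests[u$tests$compartment == "blood", ]
    tb <- tb[order(tb$adjusted_p), ]
    if (nrow(tb) && tb$v_gene[1] == "TRBV19-1" && tb$significant[1]) hits <- hits + 1L
  }
  expect_gte(hits / nrep, 0.9)
})
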