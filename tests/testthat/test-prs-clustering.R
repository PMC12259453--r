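# PRS identification, rank matrix, k-means clustering and the occurrence
# test.

ms_csf_spec <- function(...) {
  tibble::tibble(compartment = "CSF", group = "MS", ...)
}

test_that("identify_prs applies both criteria on the three-patient toy", {
  # A: top clone in P1 with count 5; B: count 1 in P1 and P2 (criterion 2);
  # C: count 1 in P1 only -> excluded by both criteria
  spec <- ms_csf_spec(
    patient_id = c("P1", "P1", "P1", "P2"),
    cdr3_aa = c("A", "B", "C", "B"),
    templates = c(5L, 1L, 1L, 1L)
  )
  prs <- identify_prs(toy_ledger(spec))
  expect_setequal(prs$cdr3_aa, c("A", "B"))
  expect_true(prs$top10_csf[prs$cdr3_aa == "A"])
  expect_false(prs$multi_patient_csf[prs$cdr3_aa == "A"])
  expect_true(prs$multi_patient_csf[prs$cdr3_aa == "B"])
  counts <- attr(prs, "counts")
  expect_equal(unname(counts), c(1L, 1L, 2L))
})

test_that("a top-ranked singleton clone found nowhere else is not a PRS", {
  spec <- ms_csf_spec(patient_id = "P1", cdr3_aa = "A", templates = 1L)
  expect_equal(nrow(identify_prs(toy_ledger(spec))), 0L)
})

test_that("ties at the top_n boundary are all included", {
  spec <- ms_csf_spec(
    patient_id = "P1",
    cdr3_aa = sprintf("S%02d", 1:12),
    templates = c(12:4, 3L, 3L, 3L)  # three-way tie at rank 10
  )
  prs <- identify_prs(toy_ledger(spec))
  expect_equal(nrow(prs), 12L)
})

test_that("identify_prs is invariant to row order and clonotype splitting", {
  spec <- ms_csf_spec(
    patient_id = c("P1", "P1", "P2"),
    cdr3_aa = c("A", "B", "B"),
    templates = c(4L, 2L, 2L)
  )
  base <- identify_prs(toy_ledger(spec))
  shuffled <- identify_prs(toy_ledger(spec[c(3, 1, 2), ]))
  expect_equal(base, shuffled, ignore_attr = TRUE)
  # split A's count over two clonotypes with the same CDR3.aa
  split <- spec[c(1, 1, 2, 3), ]
  split$templates <- c(3L, 1L, 2L, 2L)
  rr <- toy_rearrangements(split)
  rr$cdr3_nt[2] <- paste0(rr$cdr3_nt[2], "G")
  expect_equal(identify_prs(clone_ledger(rr)), base, ignore_attr = TRUE)
})

test_that("rank matrix ranks counts per sample with tie-averaged bottom ranks", {
  spec <- tibble::tibble(
    compartment = "blood", group = "MS",
    patient_id = c("P1", "P1", "P2", "P2"),
    cdr3_aa = c("A", "B", "A", "B"),
    templates = c(10L, 5L, 7L, 7L)
  )
  led <- toy_ledger(spec)
  m <- build_rank_matrix(c("A", "B", "C"), led,
                         sample_ids = c("P1_blood", "P2_blood"))
  expect_equal(unname(m[, "P1_blood"]), c(1, 2, 3))
  expect_equal(unname(m[, "P2_blood"]), c(1.5, 1.5, 3))
  counts <- attr(m, "counts")
  expect_equal(unname(counts["A", ]), c(10, 7))
  # a sample containing none of the PRS is an all-tied column
  m2 <- build_rank_matrix(c("A", "B", "C"), led,
                          sample_ids = c("P1_blood"))
  expect_equal(unname(m2[, 1]), c(1, 2, 3))
})

test_that("an all-absent sample gives the full-tie average rank", {
  spec <- tibble::tibble(
    compartment = "blood", group = "MS", patient_id = c("P1", "P2"),
    cdr3_aa = c("A", "Z"), templates = c(3L, 3L)
  )
  led <- toy_ledger(spec)
  m <- build_rank_matrix(c("A", "B", "C"), led,
                         sample_ids = c("P2_blood"))
  expect_equal(unname(m[, 1]), c(2, 2, 2))
})

test_that("rank matrix columns permute with sample relabelling", {
  spec <- tibble::tibble(
    compartment = "blood", group = "MS",
    patient_id = c("P1", "P2", "P3"),
    cdr3_aa = c("A", "B", "A"), templates = c(2L, 3L, 5L)
  )
  led <- toy_ledger(spec)
  ids <- c("P1_blood", "P2_blood", "P3_blood")
  m1 <- build_rank_matrix(c("A", "B"), led, sample_ids = ids)
  m2 <- build_rank_matrix(c("A", "B"), led, sample_ids = rev(ids))
  expect_equal(m1, m2[, ids], ignore_attr = TRUE)
})

test_that("k-means exactly recovers well-separated planted rank profiles", {
  set.seed(71)
  block1 <- matrix(rep(c(1, 2, 3, 50, 50, 50), each = 10), nrow = 10) +
    matrix(runif(60, -0.2, 0.2), 10)
  block2 <- matrix(rep(c(50, 50, 50, 1, 2, 3), each = 8), nrow = 8) +
    matrix(runif(48, -0.2, 0.2), 8)
  m <- rbind(block1, block2)
  rownames(m) <- sprintf("S%02d", 1:18)
  colnames(m) <- sprintf("D%d", 1:6)
  counts <- (m < 10) * 5  # "present" where rank small -> block1 present in MS dims
  attr(m, "counts") <- counts
  cl <- kmeans_two(m, ms_samples = c("D1", "D2", "D3"), seed = 3)
  lab <- cl$assignment$label
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:18])), 1L)
  expect_false(lab[1] == lab[11])
  # block1 is present in the MS dimensions -> it is the ms_associated cluster
  expect_equal(unique(lab[1:10]), "ms_associated")
  # deterministic given the seed
  cl2 <- kmeans_two(m, ms_samples = c("D1", "D2", "D3"), seed = 3)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("k-means objective beats random assignments on structured data", {
  set.seed(73)
  m <- matrix(rnorm(40 * 5), 40, 5)
  m[1:20, ] <- m[1:20, ] + 4
  rownames(m) <- sprintf("S%02d", 1:40)
  colnames(m) <- sprintf("D%d", 1:5)
  attr(m, "counts") <- matrix(1, 40, 5, dimnames = dimnames(m))
  cl <- kmeans_two(m, ms_samples = "D1", seed = 1)
  rand_ss <- replicate(100, {
    lab <- sample(1:2, 40, replace = TRUE)
    sum(vapply(1:2, function(k) {
      sub <- m[lab == k, , drop = FALSE]
      if (!nrow(sub)) return(0)
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, 0))
  })
  expect_lte(cl$within_ss, min(rand_ss))
})

test_that("degenerate identical profiles are rejected with advice", {
  m <- matrix(rep(c(1.5, 1.5, 3), 4), nrow = 4, byrow = TRUE)
  rownames(m) <- sprintf("S%d", 1:4); colnames(m) <- sprintf("D%d", 1:3)
  attr(m, "counts") <- matrix(1, 4, 3, dimnames = dimnames(m))
  expect_error(kmeans_two(m, ms_samples = "D1", seed = 1), "inspect")
  expect_error(kmeans_two(m[1, , drop = FALSE], "D1"), "at least 2")
})

test_that("PCA projection is deterministic with fixed signs and sane variance", {
  # rank-1 data: all rows on a line -> PC1 explains everything
  base <- c(1, 2, 3, 4)
  m <- outer(c(0, 1, 2, 5), base)
  rownames(m) <- sprintf("S%d", 1:4); colnames(m) <- sprintf("D%d", 1:4)
  pc <- pca_project(m)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)
  expect_true(sum(pc$var_explained) <= 1 + 1e-12)
  # two orthogonal clusters separate along PC1
  m2 <- rbind(matrix(rep(c(5, 5, 0, 0), 6), 6, byrow = TRUE) + rnorm(24, sd = .01),
              matrix(rep(c(0, 0, 5, 5), 6), 6, byrow = TRUE) + rnorm(24, sd = .01))
  rownames(m2) <- sprintf("S%02d", 1:12); colnames(m2) <- sprintf("D%d", 1:4)
  pc2 <- pca_project(m2)
  expect_true(max(pc2$coords$pc1[1:6]) < min(pc2$coords$pc1[7:12]) ||
                min(pc2$coords$pc1[1:6]) > max(pc2$coords$pc1[7:12]))
  expect_error(pca_project(matrix(1, 3, 3)), "zero-variance")
})

test_that("cluster occurrence test reports per-cluster Welch comparisons", {
  m <- rbind(matrix(1, 6, 4), matrix(2, 6, 4)) + matrix(runif(48), 12)
  rownames(m) <- sprintf("S%02d", 1:12); colnames(m) <- sprintf("D%d", 1:4)
  counts <- matrix(0, 12, 4, dimnames = dimnames(m))
  counts[1:6, 1:2] <- 5   # cluster A present in the two MS dims
  counts[7:12, 3:4] <- 5  # cluster B present in the two healthy dims
  attr(m, "counts") <- counts
  cl <- kmeans_two(m, ms_samples = c("D1", "D2"), seed = 2)
  oc <- cluster_occurrence_test(cl)
  ms_row <- oc[oc$label == "ms_associated", ]
  expect_equal(ms_row$mean_occ_ms, 100)
  expect_equal(ms_row$mean_occ_healthy, 0)
})
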