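# Preprocessing chain: log2(x+1), Winsorization, Z-scoring, IQR outliers,
# and the two-group comparison.

test_that("log2p1 has the stated fixed points and rejects negatives", {
  expect_equal(log2p1(0), 0)
  expect_equal(log2p1(1), 1)
  expect_equal(log2p1(7), 3)  # 2^3 - 1 = 7
  expect_equal(log2p1(c(0, 3, NA)), c(0, 2, NA))
  expect_error(log2p1(-1), "non-negative")
})

test_that("winsorize clamps to the type-7 tail quantiles", {
  expect_equal(winsorize(rep(4, 5)), rep(4, 5))
  # 8 equally spaced values: 12.5%/87.5% quantiles are 1.875 and 7.125
  expect_equal(winsorize(1:8), c(1.875, 2:7, 7.125))
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(2:30, 1))
    tp <- runif(1, 0, 0.45)
    expect_equal(winsorize(x, tp), winsorize_oracle(x, tp), tolerance = 1e-12)
  }
})

test_that("winsorize is idempotent and validates its tail probability", {
  # with interpolated (type-7) quantiles, re-winsorizing is exactly stable
  # when the tail index (n-1)*p + 1 lands on an order statistic
  set.seed(33)
  for (n in c(9, 17, 41)) {
    x <- rlnorm(n)
    w <- winsorize(x)
    expect_equal(winsorize(w), w, tolerance = 1e-12)
  }
  expect_error(winsorize(x, 0.5), "0.5")
  expect_error(winsorize(x, -0.1), "0.5")
  expect_error(winsorize(3), "two finite")
  # NA cells pass through untouched
  y <- c(NA, 1:8, NA)
  expect_equal(winsorize(y), c(NA, 1.875, 2:7, 7.125, NA))
})

test_that("zscore_rows centres and scales rows, keeping the mask", {
  m <- matrix(c(1, 3, 5, 9), 2, byrow = TRUE)
  z <- zscore_rows(m)
  expect_equal(z[1, ], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 1, sd), c(1, 1), tolerance = 1e-12)
  mm <- matrix(c(1, NA, 3, 2, 2, 2), 2, byrow = TRUE)
  expect_warning(zz <- zscore_rows(mm), "zero-variance")
  expect_true(is.na(zz[1, 2]))
  expect_equal(zz[2, ], c(0, 0, 0))
  expect_error(zscore_rows(matrix(c(1, NA, NA), 1)), "fewer than 2")
})

test_that("detect_outliers applies the Q1/Q3 +- k*IQR rule with strict bounds", {
  pan <- toy_panel(matrix(c(5, 5, 5, 5, 5,
                            1, 2, 3, 4, 100,
                            -0, 2, 3, 4, 5), ncol = 3)) # col3 benign
  pan$values[, 3] <- c(100, 2, 3, 4, 5)  # will use lower bound below
  pan$values[, 3] <- c(2, 3, 4, 5, 100)
  g <- setNames(rep("A", 5), rownames(pan$values))
  rep1 <- detect_outliers(pan, g)
  # constant analyte: IQR 0, bounds collapse, strict inequalities flag nothing
  a1 <- cytokine_categories$analyte[1]
  expect_equal(rep1$stats$n_flagged[rep1$stats$analyte == a1], 0L)
  # [1,2,3,4,100]: Q1 = 2, Q3 = 4, upper = 4 + 2*2 = 8 -> 100 flagged
  a2 <- cytokine_categories$analyte[2]
  st <- rep1$stats[rep1$stats$analyte == a2, ]
  expect_equal(c(st$q1, st$q3, st$iqr, st$upper), c(2, 4, 2, 8))
  expect_true(any(rep1$flags$analyte == a2 & rep1$flags$value == 100))
})

test_that("detect_outliers flags low outliers via Q1 - k*IQR", {
  # [0,100,101,102,103]: Q1 = 100, Q3 = 102, lower = 100 - 4 = 96 -> 0 flagged
  pan <- toy_panel(matrix(c(0, 100, 101, 102, 103,
                            1, 2, 3, 4, 5), ncol = 2))
  g <- setNames(rep("A", 5), rownames(pan$values))
  rep2 <- detect_outliers(pan, g)
  a1 <- cytokine_categories$analyte[1]
  st <- rep2$stats[rep2$stats$analyte == a1, ]
  expect_equal(c(st$q1, st$q3, st$lower), c(100, 102, 96))
  fl <- rep2$flags[rep2$flags$analyte == a1, ]
  expect_equal(unname(fl$value), 0)
  expect_equal(unname(fl$side), "low")
})

test_that("detect_outliers removes samples flagged across enough analytes", {
  set.seed(41)
  vals <- matrix(rnorm(8 * 4, 50, 1), 8, 4)
  vals[1, 1:2] <- 500  # flagged in 2 of 4 analytes -> fraction 0.5
  pan <- toy_panel(vals)
  g <- setNames(rep("A", 8), rownames(pan$values))
  rep_out <- detect_outliers(pan, g, sample_flag_fraction = 0.4)
  expect_equal(rep_out$removed_samples, "S01")
  expect_equal(nrow(rep_out$skipped), 0L)
  # with a stricter threshold the sample stays
  rep_keep <- detect_outliers(pan, g, sample_flag_fraction = 0.8)
  expect_length(rep_keep$removed_samples, 0L)
})

test_that("detect_outliers skips analytes with too few detected values", {
  vals <- matrix(rnorm(10, 50), 5, 2)
  vals[1:3, 2] <- NA
  pan <- toy_panel(vals)
  g <- setNames(rep("A", 5), rownames(pan$values))
  expect_warning(rep_out <- detect_outliers(pan, g), "skipped")
  expect_equal(rep_out$skipped$analyte, cytokine_categories$analyte[2])
})

test_that("preprocess_cytokines applies outliers -> log2p1 -> winsorize in order", {
  set.seed(43)
  vals <- matrix(rlnorm(12 * 3, 4, 0.3), 12, 3)
  pan <- toy_panel(vals)
  out <- preprocess_cytokines(pan, rownames(pan$values))
  keep <- setdiff(rownames(pan$values), out$outliers$removed_samples)
  manual <- log2p1(pan$values[keep, , drop = FALSE])
  for (j in 1:3) manual[, j] <- winsorize(manual[, j])
  expect_equal(unname(out$matrix), unname(manual), tolerance = 1e-12)
})

test_that("compare_cytokine_groups: identical groups give fold 1 and no hits", {
  vals <- matrix(rep(c(4, 7, 9, 12), 6), 8, 3)
  pan <- toy_panel(vals)
  g <- setNames(rep(c("MS", "CTRL"), each = 4), rownames(pan$values))
  res <- compare_cytokine_groups(pan, g, reference = "CTRL")
  expect_equal(res$fold_change, rep(1, 3))
  expect_true(all(res$raw_p > 0.9))
  expect_false(any(res$significant))
  expect_equal(res$adjusted_p, bh_oracle(res$raw_p))
})

test_that("compare_cytokine_groups skips analytes without enough detected data", {
  vals <- matrix(rlnorm(8 * 2, 3, 0.5), 8, 2)
  vals[1:3, 2] <- NA  # MS side keeps 1 detected value
  pan <- toy_panel(vals)
  g <- setNames(rep(c("MS", "CTRL"), each = 4), rownames(pan$values))
  vals2 <- pan$values
  vals2[1:4, 2] <- NA
  pan2 <- toy_panel(vals2)
  res <- compare_cytokine_groups(pan2, g, reference = "CTRL")
  expect_equal(attr(res, "skipped"), cytokine_categories$analyte[2])
  expect_equal(nrow(res), 1L)
})

test_that("welch test variant matches the textbook formula", {
  x <- c(3.1, 4.5, 2.2)
  y <- c(5.0, 6.1, 7.3)
  vals <- matrix(0, 6, 2)
  vals[, 1] <- c(x, y); vals[, 2] <- c(x, y) + 1
  pan <- toy_panel(vals)
  g <- setNames(rep(c("MS", "CTRL"), each = 3), rownames(pan$values))
  res <- compare_cytokine_groups(pan, g, test = "welch_t", reference = "CTRL")
  o <- welch_oracle(x, y)
  expect_equal(res$statistic[1], o$t, tolerance = 1e-12)
  expect_equal(res$raw_p[1], o$p, tolerance = 1e-12)
})
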