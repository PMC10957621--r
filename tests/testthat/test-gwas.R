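# Single-marker mixed-model scans, genomic-control inflation, thresholds,
# variance explained and plot-data export.

test_that("genomic inflation factor follows the chi-squared median ratio", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1)
  set.seed(51)
  p <- runif(100000)
  expect_equal(genomic_inflation(p), 1, tolerance = 0.02)
  # scale equivariance: inflating the chi-squared statistics by 1.5
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p_infl <- pchisq(1.5 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p_infl), 1.5, tolerance = 0.03)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "0, 1")
})

test_that("genomic-control correction deflates chi-squared quantiles", {
  # p = 0.05 at lambda = 2: chi2 3.8415 -> 1.9207 -> p 0.1658
  chi <- qchisq(0.05, 1, lower.tail = FALSE)
  expect_equal(pchisq(chi / 2, 1, lower.tail = FALSE), 0.1658, tolerance = 1e-3)

  mk_scan <- function(p) {
    res <- data.frame(marker = paste0("m", seq_along(p)), chrom = "1",
                      pos = seq_along(p), maf = 0.3, beta = 1, se = 1,
                      p_raw = p, tested = TRUE,
                      chi2 = qchisq(p, 1, lower.tail = FALSE))
    structure(list(scan = res, lambda_gc = NA, bonferroni = NULL,
                   n_tested = length(p), n_skipped = 0),
              class = "gwas_scan")
  }
  # deflated scan (lambda < 1): p-values unchanged
  set.seed(52)
  p_lo <- pbeta(runif(500), 1, 0.8)  # stochastically large p
  sc <- correct_pvalues(mk_scan(p_lo))
  if (sc$lambda_gc <= 1)
    expect_identical(sc$scan$p_corrected, sc$scan$p_raw)

  # inflated scan: corrected p >= raw p, ranks preserved
  p_hi <- pchisq(1.8 * qchisq(runif(500), 1), 1, lower.tail = FALSE)
  sc2 <- correct_pvalues(mk_scan(p_hi))
  expect_gt(sc2$lambda_gc, 1)
  expect_true(all(sc2$scan$p_corrected >= sc2$scan$p_raw - 1e-12))
  expect_identical(order(sc2$scan$p_corrected), order(sc2$scan$p_raw))
})

test_that("Bonferroni threshold is alpha over the tested marker count", {
  expect_equal(bonferroni_threshold(100)$threshold, 5e-4)
  b <- bonferroni_threshold(93170)
  expect_equal(b$threshold, 5.3665e-7, tolerance = 1e-4)
  expect_equal(b$neg_log10, 6.270, tolerance = 1e-3)
  thr <- sapply(c(10, 100, 1000), function(n) bonferroni_threshold(n)$threshold)
  expect_true(all(diff(thr) < 0))
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("percent variance explained follows the effect/se formula", {
  expect_equal(pve(0, 1, 0.3, 100), 0)
  expect_equal(pve(0.5, 0.1, 0.3, 755), 3.2, tolerance = 0.1)
  expect_gt(pve(0.5, 1e-9, 0.3, 755), 99.99)  # se -> 0 limit
  expect_error(pve(1, 0, 0.3, 100), "se > 0")
  expect_error(pve(1, 1, 0.6, 100), "maf")
})

test_that("marker effects are recovered on constructed data", {
  set.seed(53)
  gm <- hwe_panel(300, 80, n_chrom = 2)
  x <- gm$values[, 5]
  y <- setNames(2 * x + rnorm(300, 0, 0.01), rownames(gm$values))
  scan <- single_marker_scan(gm, y, correction = "loco")
  expect_equal(scan$scan$beta[5], 2, tolerance = 0.05)
  expect_lt(scan$scan$p_corrected[5], bonferroni_threshold(80)$threshold)
})

test_that("monomorphic markers are skipped and flagged", {
  set.seed(54)
  gm <- hwe_panel(60, 40, n_chrom = 2)
  gm$values[, 3] <- 0.5
  gm$p <- colMeans(gm$values)
  tr <- polygenic_trait(gm, 0.5)
  scan <- single_marker_scan(gm, tr$y)
  expect_false(scan$scan$tested[3])
  expect_true(is.na(scan$scan$p_raw[3]))
  expect_equal(scan$n_skipped, 1)
})

test_that("marker effect sign flips with allele coding", {
  set.seed(55)
  gm <- hwe_panel(150, 30, n_chrom = 2)
  tr <- polygenic_trait(gm, 0.5)
  scan1 <- single_marker_scan(gm, tr$y)
  flip <- gm
  flip$values <- 1 - gm$values
  flip$p <- 1 - gm$p
  scan2 <- single_marker_scan(flip, tr$y)
  tested <- scan1$scan$tested & scan2$scan$tested
  expect_equal(scan2$scan$beta[tested], -scan1$scan$beta[tested],
               tolerance = 1e-6)
  expect_equal(scan2$scan$p_raw[tested], scan1$scan$p_raw[tested],
               tolerance = 1e-6)
})

test_that("LOCO requires at least two chromosomes", {
  set.seed(56)
  gm <- hwe_panel(50, 20, n_chrom = 1)
  tr <- polygenic_trait(gm, 0.5)
  expect_error(single_marker_scan(gm, tr$y, correction = "loco"),
               "at least 2 chromosomes")
})

test_that("plot data export produces expected QQ quantiles and tested rows", {
  set.seed(57)
  gm <- hwe_panel(80, 60, n_chrom = 3)
  tr <- polygenic_trait(gm, 0.5)
  scan <- single_marker_scan(gm, tr$y)
  pd <- export_plots_data(scan)
  N <- scan$n_tested
  expect_equal(nrow(pd$manhattan), N)
  expect_equal(pd$qq$expected, sort(-log10((seq_len(N) - 0.5) / N)))
  expect_true(!is.unsorted(pd$qq$observed))
})

test_that("significant hits carry variance explained in (0, 100]", {
  set.seed(58)
  gm <- hwe_panel(400, 60, n_chrom = 2)
  x <- gm$values[, 10]
  y <- setNames(3 * x + rnorm(400, 0, 0.5), rownames(gm$values))
  scan <- single_marker_scan(gm, y)
  hits <- significant_hits(scan, n = 400)
  expect_gt(nrow(hits), 0)
  expect_true("M10" %in% hits$marker)
  expect_true(all(hits$pve > 0 & hits$pve <= 100))
})
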