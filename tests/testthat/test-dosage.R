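test_that("eQTL relation is assigned by the distance rule", {
  cn <- matrix(c(2, 2.5, 3, 2, 1.5, 3.5), 1, 6,
               dimnames = list("CNVR-1", paste0("s", 1:6)))
  cnp <- data.frame(name = "CNVR-1", chrom = "chr1",
                    start = 1e6, end = 1.01e6)
  expr <- matrix(rnorm(18), 3, 6,
                 dimnames = list(c("near", "far", "other_chrom"),
                                 paste0("s", 1:6)))
  gp <- data.frame(gene_id = c("near", "far", "other_chrom"),
                   chrom = c("chr1", "chr1", "chr2"),
                   start = c(1.5e6, 9e6, 1e6),
                   end = c(1.52e6, 9.1e6, 1.1e6))
  res <- eqtl_scan(cn, cnp, expr, gp, cis_window = 1e6,
                   log_transform = FALSE)
  expect_equal(res$relation[res$gene == "near"], "cis")
  expect_equal(res$distance[res$gene == "near"], 1.5e6 - 1.01e6)
  expect_equal(res$relation[res$gene == "far"], "trans")
  expect_equal(res$relation[res$gene == "other_chrom"], "trans")
  expect_true(is.infinite(res$distance[res$gene == "other_chrom"]))
})

test_that("an overlapping gene has distance zero", {
  cnp <- data.frame(name = "C", chrom = "chr1", start = 100, end = 900)
  gp <- data.frame(gene_id = "g", chrom = "chr1", start = 850, end = 2000)
  cn <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("C", paste0("s", 1:4)))
  expr <- matrix(rnorm(4), 1, 4, dimnames = list("g", paste0("s", 1:4)))
  res <- eqtl_scan(cn, cnp, expr, gp, log_transform = FALSE)
  expect_equal(res$distance, 0)
  expect_equal(res$relation, "cis")
})

test_that("eQTL slope equals the closed-form covariance ratio", {
  set.seed(37)
  n <- 24
  g <- 2 + rnorm(n, 0, 0.6)
  e <- 5 + 0.7 * g + rnorm(n, 0, 0.4)
  cn <- matrix(g, 1, n, dimnames = list("C", paste0("s", 1:n)))
  expr <- matrix(e, 1, n, dimnames = list("g", paste0("s", 1:n)))
  res <- eqtl_scan(cn, data.frame(name = "C", chrom = "1", start = 0,
                                  end = 800),
                   expr, data.frame(gene_id = "g", chrom = "1",
                                    start = 0, end = 800),
                   log_transform = FALSE)
  closed <- sum((g - mean(g)) * (e - mean(e))) / sum((g - mean(g))^2)
  expect_equal(res$effect, closed, tolerance = 1e-10)
  ref <- summary(lm(e ~ g))$coefficients[2, 4]
  expect_equal(res$p, ref, tolerance = 1e-10)
})

test_that("the generator's dosage effect is recovered by the scan", {
  co <- simulate_cohort(small_config(seed = 7))
  calls <- call_cnvrs(normalize_depth(co$depth))
  res <- eqtl_scan(calls$cn, calls$cnvrs, co$expression$values,
                   co$expression$gene_positions, log_transform = FALSE)
  hits <- overlap_sets(calls$cnvrs,
                       co$truth$cnvrs[co$truth$cnvrs$is_causal, ])
  causal_called <- calls$cnvrs$name[hits$overlapped]
  row <- res[res$cnvr %in% causal_called & res$gene == "gene_causal", ]
  row <- row[which.min(row$p), ]
  se <- abs(row$effect / row$t)
  expect_lt(abs(row$effect - 0.8), 2 * se)
  expect_lt(row$p, 0.05)
  expect_equal(row$relation, "cis")
})

test_that("null eQTL p-values are uniform and BH respects the FDR", {
  set.seed(41)
  n <- 24
  cn <- toy_cn_matrix(5, n, seed = 41, sd = 0.5)
  expr <- matrix(rnorm(200 * n, 8, 1), 200, n,
                 dimnames = list(sprintf("g%03d", 1:200), colnames(cn)))
  cnp <- data.frame(name = rownames(cn), chrom = "chr9",
                    start = seq(0, by = 1e6, length.out = 5))
  cnp$end <- cnp$start + 1e4
  gp <- data.frame(gene_id = rownames(expr), chrom = "chr1",
                   start = seq(0, by = 1e4, length.out = 200))
  gp$end <- gp$start + 5e3
  res <- eqtl_scan(cn, cnp, expr, gp, log_transform = FALSE)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(res$p_adj < 0.05, na.rm = TRUE), 0.07)
})

test_that("zero-variance pairs are skipped with a reason", {
  n <- 6
  cn <- rbind(flat = rep(2, n), ok = c(1, 2, 3, 1, 2, 3))
  colnames(cn) <- paste0("s", 1:n)
  expr <- matrix(rnorm(n), 1, n, dimnames = list("g", colnames(cn)))
  res <- eqtl_scan(cn, data.frame(name = rownames(cn), chrom = "1",
                                  start = c(0, 1e4), end = c(800, 1.1e4)),
                   expr, data.frame(gene_id = "g", chrom = "1", start = 0,
                                    end = 800),
                   log_transform = FALSE)
  expect_true(is.na(res$p[res$cnvr == "flat"]))
  expect_equal(res$skipped[res$cnvr == "flat"], "zero variance")
  expect_false(is.na(res$p[res$cnvr == "ok"]))
})

test_that("2^(-dCt) quantification follows the doubling rule", {
  expect_equal(qpcr_relative_cn(22, 22)$relative_quantity, 1)
  expect_equal(qpcr_relative_cn(22, 22)$calibrated_cn, 2)
  expect_equal(qpcr_relative_cn(21, 22)$relative_quantity, 2)
  expect_equal(qpcr_relative_cn(23, 22)$relative_quantity, 0.5)
  expect_error(qpcr_relative_cn(NA, 22), "finite")
})

test_that("qPCR round-trips the simulated copy number at zero noise", {
  cn_true <- setNames(c(1, 2, 3, 4, 2.5), paste0("p", 1:5))
  plate <- simulate_qpcr(cn_true, ct_noise_sd = 0, seed = 5)
  got <- qpcr_relative_cn(plate$ct_target, plate$ct_reference)
  expect_equal(got$calibrated_cn, unname(cn_true), tolerance = 1e-12)
  expect_error(simulate_qpcr(c(a = 0)), "positive")
})

test_that("noisy qPCR is nearly unbiased for copy number 3", {
  set.seed(55)
  plate <- simulate_qpcr(setNames(rep(3, 1000), sprintf("p%d", 1:1000)),
                         ct_noise_sd = 0.1, seed = 55)
  est <- qpcr_relative_cn(plate$ct_target, plate$ct_reference)$calibrated_cn
  expect_equal(mean(est), 3, tolerance = 0.05 / 3)
})

test_that("standard curve recovers amplification efficiency", {
  dil <- c(0, -1, -2, -3)
  r <- suppressWarnings(standard_curve(dil, 20 - 3.3219281 * dil))
  expect_equal(r$efficiency, 1, tolerance = 1e-6)
  expect_equal(r$r2, 1)
  r2 <- suppressWarnings(standard_curve(dil, 20 - 3.6 * dil))
  expect_equal(r2$efficiency, 0.8957, tolerance = 1e-4)
  expect_warning(
    r3 <- standard_curve(dil, 20 + 3.3 * dil + c(0.1, -0.1, 0.05, 0)),
    "slope")
  expect_false(r3$valid)
  expect_error(standard_curve(c(0, -1), c(20, 23)), "3 dilution")
})

test_that("group comparison handles identity, separation and degeneracy", {
  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  apart <- group_compare(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_lt(apart$p, 0.01)
  flat <- group_compare(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_true(is.na(flat$p))
})

test_that("pooled t-test type-I error is calibrated", {
  set.seed(61)
  g <- rep(c("a", "b"), each = 12)
  rej <- vapply(1:5000, function(i)
    group_compare(rnorm(24), g)$p < 0.05, logical(1))
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})

test_that("ROC AUC equals the concordant-pair fraction", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r$auc, 0.75) # 3 of 4 concordant pairs
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC of a marker and its negation sum to one exactly", {
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(x, y)$auc + roc_auc(-x, y)$auc, 1)
  }
})

test_that("AUC matches the rank statistic under ties and pROC if present", {
  x <- c(1, 1, 2, 2, 3)
  y <- c(0, 1, 0, 1, 1)
  r <- roc_auc(x, y)
  # ties counted 1/2: pairs (pos, neg): 3*2 = 6; concordant 3.5? compute:
  # oracle by explicit pair counting
  pos <- x[y == 1]; neg <- x[y == 0]
  oracle <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, oracle)
  skip_if_not_installed("pROC")
  set.seed(77)
  xs <- rnorm(60); ys <- rbinom(60, 1, 0.5)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(ys, xs,
                                                         direction = "<"))))
  expect_equal(roc_auc(xs, ys)$auc, ref, tolerance = 1e-12)
})

test_that("ROC curve endpoints and trapezoid area are consistent", {
  set.seed(79)
  x <- rnorm(40); y <- rbinom(40, 1, 0.5)
  r <- roc_auc(x, y)
  cur <- r$curve
  expect_equal(cur$sensitivity[1], 0)
  expect_equal(cur$specificity[1], 1)
  expect_equal(cur$sensitivity[nrow(cur)], 1)
  # trapezoidal area over (1-specificity, sensitivity) equals the AUC
  fpr <- 1 - cur$specificity
  area <- sum(diff(fpr) * (head(cur$sensitivity, -1) +
                             cur$sensitivity[-1]) / 2)
  expect_equal(area, r$auc, tolerance = 1e-12)
})

test_that("perfect CN-CAS association makes all three validation modes significant", {
  n <- 24
  cn <- seq(1.5, 3.5, length.out = n)
  cas <- 2 + 3 * cn
  rep <- two_step_validation(cn, cas, n_top = 12, n_bottom = 12)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$p < 0.05))
  expect_true(all(rep$mean_high > rep$mean_low))
})

test_that("validation modes keep nominal type-I error when CN and CAS are independent", {
  set.seed(83)
  rej <- matrix(NA, 5000, 3)
  for (i in 1:5000) {
    rep <- two_step_validation(rnorm(24, 2, 0.4), rnorm(24, 10, 3),
                               n_top = 12, n_bottom = 12)
    rej[i, ] <- rep$p < 0.05
  }
  rate <- colMeans(rej)
  expect_true(all(rate > 0.04 & rate < 0.06))
})

test_that("odd cohorts put the extra pig in the top half", {
  rep <- two_step_validation(1:7, 7:1)
  expect_equal(rep$n_high[rep$mode == "B_median_split_by_cn"], 4)
  expect_equal(rep$n_low[rep$mode == "B_median_split_by_cn"], 3)
})
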