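test_that("config validation catches impossible designs", {
  expect_error(simulation_config(window_size = 0), "window_size")
  expect_error(simulation_config(
    chromosome_lengths = c(chr1 = 5000)), "10 \\* window_size")
  expect_error(simulation_config(
    causal_cnvr = list(target_vst = 1.2, dosage_slope = 1)), "\\[0, 1\\]")
  expect_error(simulation_config(
    causal_cnvr = list(target_vst = 1, dosage_slope = 1, within_sd = 0.4)),
    "unreachable")
  expect_error(simulation_config(
    causal_cnvr = list(target_vst = 0.5, dosage_slope = 1, within_sd = 0)),
    "unreachable")
  expect_error(simulation_config(n_individuals = 10,
                                 n_select = c(8, 8)), "n_select")
})

test_that("a null genome has copy number 2 everywhere and unbiased estimates", {
  cfg <- simulation_config(
    n_individuals = 10, n_select = NULL,
    n_cnvrs_per_type = c(loss = 0, gain = 0, both = 0),
    causal_cnvr = NULL, depth_noise_sd = 0.05, seed = 2)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth$cnvrs), 0)
  expect_true(all(co$truth$window_cn == 2))
  cn <- normalize_depth(co$depth)
  expect_equal(mean(cn$cn), 2, tolerance = 0.05 / 2)
})

test_that("cohorts are bit-reproducible under a fixed seed", {
  a <- simulate_cohort(small_config(seed = 12))
  b <- simulate_cohort(small_config(seed = 12))
  expect_identical(a$depth$depth, b$depth$depth)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$cnvrs, b$truth$cnvrs)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$qpcr, b$qpcr)
  c <- simulate_cohort(small_config(seed = 13))
  expect_false(identical(a$depth$depth, c$depth$depth))
})

test_that("truth CNVRs are contiguous window runs; the rest is diploid", {
  co <- simulate_cohort(small_config(seed = 8))
  tr <- co$truth$cnvrs
  expect_true(all(tr$start %% 800 == 0 & tr$end %% 800 == 0))
  # mask truth regions; everything outside must be exactly 2
  win <- co$windows
  in_cnvr <- rep(FALSE, nrow(win))
  for (i in seq_len(nrow(tr)))
    in_cnvr <- in_cnvr | (win$chrom == tr$chrom[i] &
                            win$start >= tr$start[i] & win$end <= tr$end[i])
  expect_true(all(co$truth$window_cn[!in_cnvr, ] == 2))
  # inside a region each individual's copy number is constant over windows
  i1 <- which(win$chrom == tr$chrom[1] & win$start >= tr$start[1] &
                win$end <= tr$end[1])
  expect_true(all(apply(co$truth$window_cn[i1, , drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
})

test_that("constant 2-vs-4 causal clusters give realized V_ST of exactly 1", {
  cfg <- simulation_config(
    seed = 31,
    causal_cnvr = list(target_vst = 1, dosage_slope = 0.8, within_sd = 0),
    cas_model = list(baseline_rate = 10, copy_number_effect = 3,
                     residual_sd = 0))
  co <- simulate_cohort(cfg)
  cn <- co$causal$true_cn
  expect_setequal(unique(cn), c(2, 4))
  g <- setNames(as.character(co$phenotypes$group),
                co$phenotypes$pig_id)[co$sequenced]
  # cluster separation dominates the CAS, so selection splits the clusters
  expect_equal(vst(cn[g == "MAP"], cn[g == "LAP"])$vst, 1)
})

test_that("realized V_ST concentrates around the target", {
  v <- vapply(1:100, function(s) {
    co <- simulate_cohort(small_config(seed = s))
    g <- setNames(as.character(co$phenotypes$group),
                  co$phenotypes$pig_id)[co$sequenced]
    cn <- co$causal$true_cn
    vst(cn[g == "MAP"], cn[g == "LAP"])$vst
  }, numeric(1))
  expect_lt(abs(mean(v) - 0.6), 0.1)
})

test_that("realized V_ST increases with the configured target", {
  mean_realized <- function(t) {
    mean(vapply(1:25, function(s) {
      co <- simulate_cohort(simulation_config(
        seed = s, causal_cnvr = list(target_vst = t, dosage_slope = 0.8,
                                     within_sd = 0.4)))
      g <- setNames(as.character(co$phenotypes$group),
                    co$phenotypes$pig_id)[co$sequenced]
      cn <- co$causal$true_cn
      vst(cn[g == "MAP"], cn[g == "LAP"])$vst
    }, numeric(1)))
  }
  grid <- vapply(c(0.4, 0.6, 0.8, 0.95), mean_realized, numeric(1))
  expect_true(all(diff(grid) > 0))
})

test_that("expected CAS increases with causal copy number", {
  co <- simulate_cohort(small_config(seed = 14))
  ph <- co$phenotypes
  cn <- setNames(rep(2, nrow(ph)), ph$pig_id)
  cn[names(co$causal$true_cn)] <- co$causal$true_cn
  # herd-level regression of CAS on causal CN should be clearly positive
  fit <- summary(lm(ph$cas ~ cn[ph$pig_id]))
  expect_gt(fit$coefficients[2, 1], 0)
  expect_lt(fit$coefficients[2, 4], 0.01)
  # attack records respect the duration-zero invariant
  expect_true(all(ph$attack_duration_s[ph$attack_count == 0] == 0))
  expect_equal(ph$cas, composite_aggressive_score(ph$attack_count,
                                                  ph$attack_duration_s))
})

test_that("null dosage slope leaves expression uncorrelated with copy number", {
  co <- simulate_cohort(small_config(seed = 9))
  cors <- vapply(1:1000, function(i) {
    e <- simulate_expression(co, dosage_slope = 0, residual_sd = 1,
                             seed = i)
    cor(e$values["gene_causal", ], co$causal$true_cn)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("zero residual makes expression perfectly collinear with dosage", {
  co <- simulate_cohort(small_config(seed = 10))
  e <- simulate_expression(co, dosage_slope = 1, residual_sd = 0, seed = 3)
  expect_equal(cor(e$values["gene_causal", ], co$causal$true_cn), 1)
})

test_that("OLS confidence intervals cover the simulated dosage slope", {
  co <- simulate_cohort(small_config(seed = 7))
  cn <- co$causal$true_cn
  covered <- vapply(1:500, function(i) {
    e <- simulate_expression(co, dosage_slope = 0.8, residual_sd = 0.5,
                             seed = i)
    fit <- summary(lm(e$values["gene_causal", ] ~ cn))
    est <- fit$coefficients[2, 1]; se <- fit$coefficients[2, 2]
    crit <- qt(0.975, df = fit$df[2])
    (est - crit * se) <= 0.8 && 0.8 <= (est + crit * se)
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("an unknown affected gene is rejected", {
  co <- simulate_cohort(small_config(seed = 11))
  co$causal$affected_gene <- "no_such_gene"
  expect_error(simulate_expression(co, 0.8, 0.5, seed = 1), "no_such_gene")
})
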