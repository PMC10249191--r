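test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_informative = 50, n_genes = 20),
               "n_informative")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(positive_rate = 1.2), "positive_rate")
  expect_error(synthetic_config(n_cnv_states = 1), "n_cnv_states")
  expect_error(synthetic_config(missing_rate_range = c(0, 1.5)),
               "missing_rate_range")
  expect_error(synthetic_config(modality_dropout = 1), "modality_dropout")
})

test_that("identical seed gives a bit-identical cohort", {
  cfg <- synthetic_config(n_labelled = 60, n_unlabelled = 80, n_genes = 40,
                          n_informative = 5, n_cnv_genes = 30,
                          n_clinical_cols = 4, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$labels, b$labels)
  expect_identical(unclass(a$expression), unclass(b$expression))
  expect_identical(unclass(a$cnv), unclass(b$cnv))
  expect_identical(unclass(a$clinical), unclass(b$clinical))
  expect_identical(unclass(a$unlabelled), unclass(b$unlabelled))
})

test_that("null expression (effect 0) yields calibrated t-test p-values", {
  cfg <- synthetic_config(n_labelled = 500, n_genes = 1200,
                          n_informative = 10, effect_size = 0, seed = 5)
  set.seed(50)
  y <- rep(c(0L, 1L), 250)
  X <- generate_expression(cfg, y)
  sel <- ttest_select(X, y, alpha = 0.05)
  p <- sel$scores
  # rejection rate ~ alpha within 3 binomial SDs
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1200))
  # p-values uniform (KS at alpha 0.01)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted genes at d=2 are all detected with 200 per class", {
  cfg <- synthetic_config(n_labelled = 400, n_genes = 300,
                          n_informative = 10, effect_size = 2,
                          positive_rate = 0.5, seed = 8)
  y <- rep(c(0L, 1L), 200)
  X <- generate_expression(cfg, y)
  truth <- attr(X, "truth")$informative
  sel <- ttest_select(X, y, alpha = 0.01)
  expect_true(all(truth %in% sel$selected_ids))
})

test_that("cnv values stay in range and label-linked genes rank first", {
  cfg <- synthetic_config(n_labelled = 300, n_cnv_genes = 120,
                          n_cnv_states = 5, n_cnv_informative = 3, seed = 3)
  set.seed(33)
  y <- rbinom(300, 1, 0.3)
  C <- generate_cnv(cfg, y)
  expect_true(all(C %in% 0:4))
  truth <- attr(C, "truth")$informative
  sel <- chi2_select(C, y, k = 3)
  expect_setequal(sel$selected_ids, truth)
})

test_that("label-independent cnv chi-squared scores look null", {
  cfg <- synthetic_config(n_labelled = 400, n_cnv_genes = 500,
                          n_cnv_informative = 0, seed = 13)
  set.seed(14)
  y <- rbinom(400, 1, 0.3)
  C <- generate_cnv(cfg, y)
  stats_ <- chi2_select(C, y, k = 1)$scores
  # under independence the statistics have mean ~ df (at most states-1)
  expect_lt(mean(stats_), 5)
  expect_gt(mean(stats_), 2)
})

test_that("clinical missingness spans the configured range", {
  cfg <- synthetic_config(n_labelled = 400, n_clinical_cols = 8,
                          missing_rate_range = c(0.05, 0.95), seed = 9)
  M <- generate_clinical(cfg)
  fr <- colMeans(is.na(M))
  expect_gt(max(fr), 0.5)   # at least one column beyond a 0.5 threshold
  expect_lt(min(fr), 0.3)
  cfg0 <- synthetic_config(n_labelled = 50, n_clinical_cols = 4,
                           missing_rate_range = c(0, 0), seed = 9)
  expect_false(anyNA(generate_clinical(cfg0)))
})

test_that("modality dropout controls the fused intersection", {
  cfg0 <- synthetic_config(n_labelled = 80, n_unlabelled = 40, n_genes = 30,
                           n_informative = 4, n_cnv_genes = 25,
                           n_clinical_cols = 3, modality_dropout = 0,
                           seed = 2)
  coh0 <- generate_cohort(cfg0)
  ids <- Reduce(intersect, list(rownames(coh0$expression),
                                rownames(coh0$cnv),
                                rownames(coh0$clinical)))
  expect_length(ids, 80)

  cfg1 <- synthetic_config(n_labelled = 600, n_unlabelled = 40, n_genes = 30,
                           n_informative = 4, n_cnv_genes = 25,
                           n_clinical_cols = 3, modality_dropout = 0.1,
                           seed = 2)
  coh1 <- generate_cohort(cfg1)
  n_int <- length(Reduce(intersect, list(rownames(coh1$expression),
                                         rownames(coh1$cnv),
                                         rownames(coh1$clinical))))
  # independent Bernoulli keep ~ Binomial(600, 0.9^3)
  expected <- 600 * 0.9^3
  expect_lt(abs(n_int - expected), 4 * sqrt(600 * 0.9^3 * (1 - 0.9^3)))
})

test_that("unlabelled corpus shares the labelled gene schema", {
  cfg <- synthetic_config(n_labelled = 40, n_unlabelled = 60, n_genes = 25,
                          n_informative = 3, n_cnv_genes = 20,
                          n_clinical_cols = 3, seed = 4)
  coh <- generate_cohort(cfg)
  expect_identical(colnames(coh$unlabelled), colnames(coh$expression))
  expect_equal(nrow(coh$unlabelled), 60)
  expect_true(all(coh$expression >= 0))
  expect_length(coh$truth$expression, 3)
})
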