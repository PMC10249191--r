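test_that("t-test selection recovers strong planted signal and rejects noise", {
  td <- toy_signal_data(n = 400, p = 50, n_inf = 5, d = 2, seed = 11)
  sel <- ttest_select(td$x, td$y, alpha = 0.01)
  expect_true(all(sprintf("F%02d", 1:5) %in% sel$selected_ids))
  # selected ids come back in original column order
  expect_identical(sel$selected_ids,
                   colnames(td$x)[colnames(td$x) %in% sel$selected_ids])
})

test_that("t-test null calibration under permuted labels", {
  set.seed(21)
  x <- matrix(rnorm(200 * 2000), 200, 2000,
              dimnames = list(sprintf("P%03d", 1:200),
                              sprintf("F%04d", 1:2000)))
  y <- rep(c(0L, 1L), 100)
  sel <- ttest_select(x, sample(y), alpha = 0.01)
  rate <- length(sel$selected_ids) / 2000
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 2000))
})

test_that("constant features are excluded from t-test selection", {
  td <- toy_signal_data(n = 60, p = 5, seed = 3)
  td$x[, 4] <- 1
  expect_message(sel <- ttest_select(td$x, td$y, alpha = 0.5), "constant")
  expect_false("F04" %in% sel$selected_ids)
})

test_that("lasso selection honours the penalty limit and finds the signal", {
  td <- toy_signal_data(n = 200, p = 10, n_inf = 1, d = 4, seed = 5)
  # essentially infinite penalty: nothing survives
  sel0 <- lasso_select(td$x, td$y, inv_reg = 1e-9)
  expect_length(sel0$selected_ids, 0)
  # moderate penalty on one dominant feature: exactly that feature
  sel1 <- lasso_select(td$x, td$y, inv_reg = 0.05)
  expect_identical(sel1$selected_ids, "F01")
})

test_that("lasso selection is invariant to column order", {
  td <- toy_signal_data(n = 150, p = 12, n_inf = 3, d = 1.5, seed = 6)
  sel_a <- lasso_select(td$x, td$y, inv_reg = 0.1)
  perm <- sample(ncol(td$x))
  sel_b <- lasso_select(td$x[, perm], td$y, inv_reg = 0.1)
  expect_setequal(sel_a$selected_ids, sel_b$selected_ids)
})

test_that("pca retains the minimal components for the variance target", {
  expect_error(pca_fit(toy_signal_data()$x, variance_target = 0), "variance_target")
  # exactly planar data in 10-D: two components explain everything
  set.seed(7)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  x <- matrix(rnorm(80 * 2), 80, 2) %*% t(basis)
  dimnames(x) <- list(sprintf("P%02d", 1:80), sprintf("F%02d", 1:10))
  sel <- pca_fit(x, variance_target = 0.999)
  expect_equal(ncol(sel$projection$rotation), 2)
  # full target keeps rank(X) components
  sel1 <- pca_fit(x, variance_target = 1.0)
  expect_equal(ncol(sel1$projection$rotation), 2)
})

test_that("pca reconstruction error respects the retained variance", {
  set.seed(8)
  x <- matrix(rnorm(60 * 15), 60, 15,
              dimnames = list(sprintf("P%02d", 1:60),
                              sprintf("F%02d", 1:15)))
  target <- 0.9
  sel <- pca_fit(x, variance_target = target)
  z <- apply_selection(sel, x)
  xs <- scale(x, sel$projection$center, sel$projection$scale)
  recon <- unclass(z) %*% t(sel$projection$rotation)
  err <- sum((xs - recon)^2)
  expect_lte(err, (1 - target) * sum(xs^2) + 1e-8)
})

test_that("variance top-k ranks by variance with stable ties", {
  x <- cbind(F1 = rep(1, 4), F2 = c(0, 1, 0, 1) * 2, F3 = c(0, 2, 4, 6))
  rownames(x) <- sprintf("P%d", 1:4)
  sel <- variance_top_k(x, 2)
  expect_identical(sel$selected_ids, c("F3", "F2"))  # variances 0, 4/3*? , larger
  expect_error(variance_top_k(x, 5), "exceeds")
  expect_identical(variance_top_k(x, 3)$selected_ids[3], "F1")
})

test_that("chi-squared scoring matches the hand-computed 2x2 table", {
  x <- cbind(F1 = rep(c(0, 1), each = 10))
  rownames(x) <- sprintf("P%02d", 1:20)
  y <- rep(c(0L, 1L), each = 10)
  sel <- chi2_select(x, y, k = 1)
  # table (10,0 / 0,10): chi-squared = 20
  expect_equal(unname(sel$scores["F1"]), 20, tolerance = 1e-12)
})

test_that("a label-identical feature outranks all others", {
  set.seed(9)
  y <- rep(c(0L, 1L), 30)
  x <- cbind(matrix(sample(0:3, 60 * 5, TRUE), 60, 5),
             exact = y)
  colnames(x) <- c(sprintf("F%d", 1:5), "exact")
  rownames(x) <- sprintf("P%02d", 1:60)
  sel <- chi2_select(x, y, k = 6)
  expect_identical(sel$selected_ids[1], "exact")
  # single-category feature scores zero
  x2 <- cbind(x, flat = 1L)
  rownames(x2) <- rownames(x)
  expect_equal(unname(chi2_select(x2, y, k = 1)$scores["flat"]), 0)
})

test_that("apply_selection transfers, drops extras, errors on missing", {
  td <- toy_signal_data(n = 80, p = 6, n_inf = 2, d = 2, seed = 10)
  sel <- ttest_select(td$x, td$y, alpha = 0.05)
  same <- apply_selection(sel, td$x)
  expect_identical(colnames(same), sel$selected_ids)
  # extra features dropped silently
  wide <- cbind(td$x, EXTRA = rnorm(80))
  rownames(wide) <- rownames(td$x)
  expect_identical(unclass(apply_selection(sel, wide)), unclass(same))
  # missing feature is an error listing the id
  slim <- td$x[, setdiff(colnames(td$x), sel$selected_ids[1])]
  expect_error(apply_selection(sel, slim), sel$selected_ids[1], fixed = TRUE)
})

test_that("pca projection carries no statistics from held-out data", {
  set.seed(12)
  x_fit <- matrix(rnorm(50 * 8), 50, 8,
                  dimnames = list(sprintf("A%02d", 1:50),
                                  sprintf("F%02d", 1:8)))
  x_new <- matrix(rnorm(30 * 8, mean = 5), 30, 8,
                  dimnames = list(sprintf("B%02d", 1:30),
                                  sprintf("F%02d", 1:8)))
  sel <- pca_fit(x_fit, 0.999)
  z <- apply_selection(sel, x_new)
  # transform must use fit-time centering: a mean-5 shift survives
  expect_gt(max(abs(colMeans(unclass(z)))), 1)
})
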