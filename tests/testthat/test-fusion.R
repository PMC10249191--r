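mk_clin <- function(m, ids = sprintf("P%02d", seq_len(nrow(m)))) {
  rownames(m) <- ids
  omics_matrix(m, "clinical")
}

test_that("clinical columns above the missingness threshold are dropped", {
  set.seed(1)
  m <- cbind(keep_cat = sample(0:2, 40, TRUE),
             drop_me = ifelse(runif(40) < 0.9, NA, 1),
             keep_num = rnorm(40))
  x <- mk_clin(m)
  out <- preprocess_clinical(x, max_missing = 0.5)
  expect_false("drop_me" %in% colnames(out))
  expect_true(all(c("keep_cat", "keep_num") %in% colnames(out)))
  expect_error(preprocess_clinical(mk_clin(cbind(a = rep(NA_real_, 5))), 0.5),
               "threshold")
})

test_that("encoding without missing values is a pure relabeling", {
  m <- cbind(stage = c(2, 0, 1, 2, 0), grade = c(5, 7, 5, 7, 5))
  x <- mk_clin(m)
  out <- preprocess_clinical(x, max_missing = 0.5)
  expect_equal(ncol(out), 2)
  expect_false(anyNA(out))
  # codes preserve level order
  expect_equal(unname(out[, "stage"]), c(2, 0, 1, 2, 0))
  expect_equal(unname(out[, "grade"]), c(0, 1, 0, 1, 0))
})

test_that("missing entries get a dedicated category", {
  m <- cbind(stage = c(0, 1, NA, 1, NA))
  x <- mk_clin(m)
  out <- preprocess_clinical(x, max_missing = 0.6)
  # levels 0,1 -> codes 0,1; missing -> code 2
  expect_equal(unname(out[, "stage"]), c(0, 1, 2, 1, 2))
})

test_that("a designed fixture retains exactly five clinical columns", {
  set.seed(2)
  n <- 60
  m <- cbind(age = rnorm(n, 60, 10),
             sex = sample(0:1, n, TRUE),
             stage = sample(0:3, n, TRUE),
             prior_tx = sample(0:1, n, TRUE),
             ethnicity = sample(0:4, n, TRUE),
             sparse1 = ifelse(runif(n) < 0.8, NA, 1),
             sparse2 = ifelse(runif(n) < 0.95, NA, 0))
  out <- preprocess_clinical(mk_clin(m), max_missing = 0.5)
  expect_equal(ncol(out), 5)
})

test_that("cnv reduction composes variance and chi-squared stages", {
  cfg <- synthetic_config(n_labelled = 200, n_cnv_genes = 3000,
                          n_cnv_informative = 5, seed = 17)
  set.seed(18)
  y <- rbinom(200, 1, 0.25)
  C <- generate_cnv(cfg, y)
  sel <- preprocess_cnv(C, y, top_var = 2000, top_chi2 = 256)
  expect_length(sel$selected_ids, 256)
  expect_error(preprocess_cnv(C, y, top_var = 100, top_chi2 = 200),
               "top_chi2")
  # a planted high-variance, label-dependent gene survives both stages
  truth <- attr(C, "truth")$informative
  expect_true(length(intersect(truth, sel$selected_ids)) >= 4)
})

test_that("fusion keeps only the submitter-ID intersection", {
  ex <- omics_matrix(matrix(1:6, 3, 2,
                            dimnames = list(c("A", "B", "C"), c("g1", "g2"))),
                     "expression")
  cn <- omics_matrix(matrix(1:6, 3, 2,
                            dimnames = list(c("B", "C", "D"), c("c1", "c2"))),
                     "cnv")
  cl <- omics_matrix(matrix(1:2, 1, 2,
                            dimnames = list("C", c("k1", "k2"))),
                     "clinical")
  fd <- match_and_fuse(ex, cn, cl)
  expect_identical(rownames(fd$matrix), "C")
  expect_equal(fd$manifest$intersection, 1)
  # empty intersection errors with per-modality counts
  cl2 <- omics_matrix(matrix(1, 1, 1, dimnames = list("Z", "k1")), "clinical")
  expect_error(match_and_fuse(ex, cn, cl2), "empty")
})

test_that("fused width accounts for every block", {
  set.seed(3)
  ids <- sprintf("P%03d", 1:50)
  ex <- omics_matrix(matrix(rnorm(50 * 230), 50, 230,
                            dimnames = list(ids, sprintf("E%03d", 1:230))),
                     "expression")
  cn <- omics_matrix(matrix(sample(0:4, 50 * 256, TRUE), 50, 256,
                            dimnames = list(ids, sprintf("C%03d", 1:256))),
                     "cnv")
  cl <- omics_matrix(matrix(sample(0:2, 50 * 5, TRUE), 50, 5,
                            dimnames = list(ids, sprintf("K%d", 1:5))),
                     "clinical")
  lab <- stats::setNames(rep(c(0L, 1L), 25), ids)
  fd <- match_and_fuse(ex, cn, cl, labels = lab)
  expect_equal(ncol(fd$matrix), 230 + 256 + 5)
  expect_equal(unname(unlist(fd$manifest$block_widths)),
               c(230L, 256L, 5L))
  expect_equal(nrow(fd$block_index), 491)
  expect_identical(names(fd$labels), rownames(fd$matrix))
})

test_that("fusion never alters a value and is row-order invariant", {
  set.seed(4)
  ids <- sprintf("P%02d", 1:20)
  ex <- omics_matrix(matrix(rnorm(20 * 6), 20, 6,
                            dimnames = list(ids, sprintf("E%d", 1:6))),
                     "expression")
  cn <- omics_matrix(matrix(sample(0:4, 20 * 4, TRUE), 20, 4,
                            dimnames = list(ids, sprintf("C%d", 1:4))),
                     "cnv")
  cl <- omics_matrix(matrix(rnorm(20 * 2), 20, 2,
                            dimnames = list(ids, sprintf("K%d", 1:2))),
                     "clinical")
  fd <- match_and_fuse(ex, cn, cl)
  # random probes equal their source cells
  for (i in 1:20) {
    r <- sample(rownames(fd$matrix), 1)
    j <- sample(nrow(fd$block_index), 1)
    src <- fd$block_index[j, ]
    source_mat <- list(expression = ex, cnv = cn, clinical = cl)[[src$modality]]
    expect_identical(as.numeric(fd$matrix[r, src$column]),
                     as.numeric(source_mat[r, src$feature_id]))
  }
  # canonical output order regardless of input row order
  shuf <- function(m) m[sample(nrow(m)), , drop = FALSE]
  fd2 <- match_and_fuse(shuf(ex), shuf(cn), shuf(cl))
  expect_identical(unclass(fd$matrix), unclass(fd2$matrix))
})

test_that("duplicate feature IDs across blocks require prefixing", {
  ids <- sprintf("P%d", 1:5)
  a <- omics_matrix(matrix(1:10, 5, 2, dimnames = list(ids, c("g1", "g2"))),
                    "expression")
  b <- omics_matrix(matrix(rep(1L, 10), 5, 2,
                           dimnames = list(ids, c("g1", "g2"))), "cnv")
  cl <- omics_matrix(matrix(1, 5, 1, dimnames = list(ids, "k1")), "clinical")
  expect_error(match_and_fuse(a, b, cl, prefix = FALSE), "duplicate")
  fd <- match_and_fuse(a, b, cl, prefix = TRUE)
  expect_true(all(c("expr|g1", "cnv|g1") %in% colnames(fd$matrix)))
})
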