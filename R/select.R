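#' @title Feature-reduction strategies for high-dimensional omics matrices
#' @description
#' Fitted selections are `selection_result` objects carrying the method,
#' its parameters, the ordered selected feature IDs (or a PCA projection),
#' and the full feature list seen at fit time, so that exactly the same
#' reduction can be transferred to another matrix (e.g. an unlabelled
#' corpus) with [apply_selection()].
#' @name feature_selection
NULL

new_selection_result <- function(method, params, selected_ids,
                                 fit_feature_ids, projection = NULL,
                                 scores = NULL) {
  structure(list(method = method, params = params,
                 selected_ids = selected_ids,
                 fit_feature_ids = fit_feature_ids,
                 projection = projection, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %s; %s -> %s features\n", x$method,
              length(x$fit_feature_ids),
              if (x$method == "pca") paste0(ncol(x$projection$rotation), " components")
              else length(x$selected_ids)))
  invisible(x)
}

check_binary_y <- function(y, n) {
  if (length(y) != n) stop("labels must match the number of samples")
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  invisible(as.integer(y))
}

#' Two-sample t-test feature selection
#'
#' Selects features whose two-sided two-sample t-test p-value between the
#' classes falls below `alpha`, in original column order. Welch's
#' unequal-variance form is the default; Student's pooled-variance form
#' is available via `var_equal`. No multiple-testing correction is
#' applied by default (the raw cutoff is the conventional rule for this screen); an optional
#' Benjamini-Hochberg switch adjusts the p-values first.
#'
#' @param X samples x features `OmicsMatrix` (or matrix).
#' @param y binary labels (0/1), one per row of `X`.
#' @param alpha significance cutoff in (0,1); default 0.01.
#' @param var_equal use the pooled-variance (Student) statistic.
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding.
#' @return a `selection_result` (method `"ttest"`) whose `scores` element
#'   holds the per-feature p-values.
#' @export
ttest_select <- function(X, y, alpha = 0.01, var_equal = FALSE, fdr = FALSE) {
  y <- check_binary_y(y, nrow(X))
  if (alpha <= 0 || alpha >= 1) stop("ttest_select: alpha must be in (0,1)")
  if (min(table(y)) < 2) stop("ttest_select: each class needs at least 2 samples")
  x <- as_plain(X)
  g1 <- x[y == 1, , drop = FALSE]
  g0 <- x[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, stats::var); v0 <- apply(g0, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, ncol(x))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- !is.finite(p)          # constant in both groups: undefined
  if (any(degenerate)) {
    message("ttest_select: excluding ", sum(degenerate),
            " feature(s) constant in both groups")
    p[degenerate] <- 1
  }
  padj <- if (fdr) stats::p.adjust(p, "BH") else p
  sel <- colnames(X)[padj < alpha]
  new_selection_result("ttest",
                       list(alpha = alpha, var_equal = var_equal, fdr = fdr),
                       sel, colnames(X),
                       scores = stats::setNames(p, colnames(X)))
}

# column standardization fitted on the (labelled) data at hand
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

#' L1-penalized logistic feature selection
#'
#' Fits an L1 logistic model at a single penalty determined by the
#' inverse regularisation strength `inv_reg` (the sklearn-style `C`;
#' internally `lambda = 1/(n * C)` so the objective matches) on
#' standardized columns, then selects the features with non-zero
#' coefficients. The solver is glmnet's coordinate descent, warm-started
#' along a decreasing lambda path for stability.
#'
#' @inheritParams ttest_select
#' @param inv_reg inverse regularisation strength; default 0.001 (strong
#'   penalty, few survivors).
#' @param coef_tol magnitude below which a coefficient counts as zero.
#' @param maxit coordinate-descent iteration cap.
#' @return a `selection_result` (method `"lasso"`).
#' @export
lasso_select <- function(X, y, inv_reg = 0.001, coef_tol = 1e-8,
                         maxit = 1e5) {
  y <- check_binary_y(y, nrow(X))
  if (inv_reg <= 0) stop("lasso_select: inv_reg must be positive")
  x <- as_plain(X)
  std <- fit_standardizer(x)
  xs <- scale(x, std$center, std$scale)
  lam <- 1 / (nrow(x) * inv_reg)
  lam_path <- exp(seq(log(lam * 100), log(lam), length.out = 20))
  fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                        lambda = lam_path, standardize = FALSE,
                        maxit = maxit)
  if (fit$jerr != 0)
    stop("lasso_select: solver did not converge within ", maxit,
         " iterations (jerr = ", fit$jerr, ")")
  cf <- as.numeric(stats::coef(fit, s = lam))[-1]   # drop intercept
  sel <- colnames(X)[abs(cf) > coef_tol]
  new_selection_result("lasso",
                       list(inv_reg = inv_reg, coef_tol = coef_tol),
                       sel, colnames(X),
                       scores = stats::setNames(cf, colnames(X)))
}

#' Principal-component projection retaining a variance fraction
#'
#' Centers and standardizes columns (statistics from the fitting data
#' only) and retains the minimal number of leading components whose
#' cumulative explained variance reaches `variance_target`.
#'
#' @param X samples x features matrix.
#' @param variance_target fraction of variance to retain, in (0,1];
#'   default 0.999.
#' @return a `selection_result` (method `"pca"`) whose `projection`
#'   carries the rotation, centering and scaling vectors.
#' @export
pca_fit <- function(X, variance_target = 0.999) {
  if (variance_target <= 0 || variance_target > 1)
    stop("pca_fit: variance_target must be in (0, 1]")
  if (nrow(X) < 2) stop("pca_fit: need at least 2 samples")
  x <- as_plain(X)
  std <- fit_standardizer(x)
  pc <- stats::prcomp(scale(x, std$center, std$scale),
                      center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev / sum(ev)
  ncomp <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  new_selection_result("pca", list(variance_target = variance_target),
                       character(0), colnames(X),
                       projection = list(rotation = rot,
                                         center = std$center,
                                         scale = std$scale,
                                         explained = ev[seq_len(ncomp)]))
}

#' Top-k features by variance
#'
#' @param X samples x features matrix.
#' @param k number of features to keep; ties broken by original column
#'   order.
#' @return a `selection_result` (method `"variance_topk"`); selected IDs
#'   in decreasing-variance order.
#' @export
variance_top_k <- function(X, k) {
  if (k > ncol(X)) stop("variance_top_k: k exceeds the number of features")
  if (k < 1) stop("variance_top_k: k must be positive")
  v <- apply(as_plain(X), 2, stats::var)
  ord <- order(-v, seq_along(v))       # stable: ties by column order
  sel <- colnames(X)[ord[seq_len(k)]]
  new_selection_result("variance_topk", list(k = k), sel, colnames(X),
                       scores = stats::setNames(v, colnames(X)))
}

# Pearson chi-squared statistic of the category x label table, no
# continuity correction; single-category features score 0 by convention.
chi2_stat <- function(x, y) {
  tab <- table(x, y)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' Top-k categorical features by chi-squared association with the label
#'
#' Scores each (categorical, non-negative integer coded) feature by the
#' Pearson chi-squared statistic of its category x label contingency
#' table and keeps the `k` highest-scoring features.
#'
#' @inheritParams ttest_select
#' @param k number of features to keep.
#' @return a `selection_result` (method `"chi2_topk"`); selected IDs in
#'   decreasing-statistic order, ties by original column order.
#' @export
chi2_select <- function(X, y, k) {
  y <- check_binary_y(y, nrow(X))
  if (k > ncol(X)) stop("chi2_select: k exceeds the number of features")
  x <- as_plain(X)
  if (any(x < 0)) stop("chi2_select: features must be non-negative categories")
  stat <- apply(x, 2, chi2_stat, y = y)
  ord <- order(-stat, seq_along(stat))
  sel <- colnames(X)[ord[seq_len(k)]]
  new_selection_result("chi2_topk", list(k = k), sel, colnames(X),
                       scores = stats::setNames(stat, colnames(X)))
}

#' Apply a fitted selection to a (possibly different) matrix
#'
#' Transfers a reduction fitted on labelled data to any matrix with
#' matching features — e.g. the unlabelled corpus. ID-based selections
#' subset columns in the stored order (extra features in `X` are dropped
#' silently; missing ones are an error). PCA applies the stored
#' standardization and rotation.
#'
#' @param sel a `selection_result`.
#' @param X samples x features matrix containing the required features.
#' @return an `OmicsMatrix` of the reduced data.
#' @export
apply_selection <- function(sel, X) {
  stopifnot(inherits(sel, "selection_result"))
  mod <- if (inherits(X, "OmicsMatrix")) modality(X) else "expression"
  if (sel$method == "pca") {
    need <- sel$fit_feature_ids
    miss <- setdiff(need, colnames(X))
    if (length(miss))
      stop("apply_selection: matrix lacks feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) " ..." else "")
    x <- as_plain(X)[, need, drop = FALSE]
    xs <- scale(x, sel$projection$center, sel$projection$scale)
    out <- xs %*% sel$projection$rotation
    rownames(out) <- rownames(X)
    return(omics_matrix(out, mod))
  }
  miss <- setdiff(sel$selected_ids, colnames(X))
  if (length(miss))
    stop("apply_selection: matrix lacks feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "")
  out <- as_plain(X)[, sel$selected_ids, drop = FALSE]
  omics_matrix(out, mod)
}
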