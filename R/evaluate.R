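#' ROC-AUC by the rank (Mann-Whitney) formulation
#'
#' The probability that a randomly chosen positive receives a higher
#' score than a randomly chosen negative, with ties counted one half.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param y binary labels (0/1).
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  if (length(scores) != length(y)) stop("roc_auc: length mismatch")
  if (!all(y %in% c(0, 1))) stop("roc_auc: labels must be binary 0/1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' into the folds, so every fold's class ratio is within one sample of
#' the global ratio and the partition is exact.
#'
#' @param y binary labels (0/1).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratified set `FALSE` for a plain shuffled split.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L, stratified = TRUE) {
  n <- length(y)
  set.seed(seed)
  folds <- integer(n)
  if (stratified) {
    if (min(table(y)) < k)
      stop("stratified_folds: minority class smaller than k")
    offset <- 0L
    for (cl in sort(unique(y), decreasing = TRUE)) {
      idx <- sample(which(y == cl))
      # continue the fold counter across classes so total fold sizes
      # stay within one sample of each other as well
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  } else {
    folds <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  folds
}

#' Wrap a learner behind the uniform fit/score contract
#'
#' @param fit function(X, y) returning a fitted object.
#' @param score function(fitted, X) returning scores in `[0, 1]`.
#' @param label short description used in reports.
#' @return a `learner` list.
#' @export
learner <- function(fit, score, label = "learner") {
  structure(list(fit = fit, score = score, label = label),
            class = "learner")
}

#' Learner from a baseline specification
#'
#' @param spec a [baseline_spec()].
#' @return a `learner`.
#' @export
baseline_learner <- function(spec) {
  learner(fit = function(X, y) fit_baseline(spec, X, y),
          score = function(m, X) score(m, X),
          label = spec$family)
}

#' Learner for the sequential-attention network
#'
#' With `pretrained_model` supplied, each fold's fit starts from the
#' pretrained encoder weights (fitted on the unlabelled corpus only, so
#' no test-fold leakage); otherwise each fold trains from a cold start.
#'
#' @param config an [ssl_config()].
#' @param pretrained_model optional [pretrain()] output.
#' @return a `learner`.
#' @export
tabnet_learner <- function(config = ssl_config(), pretrained_model = NULL) {
  learner(
    fit = function(X, y) {
      base <- if (is.null(pretrained_model)) tabnet_new(X, config)
              else pretrained_model
      finetune(base, X, y, config = config)
    },
    score = function(m, X) predict(m, X),
    label = if (is.null(pretrained_model)) "tabnet_cold" else "tabnet_ssl")
}

# cheap stable hash for config provenance (FNV-1a over serialized bytes)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Stratified k-fold cross-validated ROC-AUC
#'
#' Freshly fits the learner on each training fold and scores the held-out
#' fold; reports the per-fold ROC-AUCs with their arithmetic mean and
#' sample standard deviation.
#'
#' @param lrn a [learner()] (see [baseline_learner()],
#'   [tabnet_learner()]).
#' @param X samples x features matrix.
#' @param y binary labels (0/1).
#' @param k folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param stratified stratify folds by class (default `TRUE`).
#' @return a `cv_report`: `fold_scores`, `mean`, `sd`,
#'   `fold_assignments`, `config_hash`, `seed`, `label`.
#' @export
cross_validate <- function(lrn, X, y, k = 5L, seed = 1L,
                           stratified = TRUE) {
  stopifnot(inherits(lrn, "learner"))
  y <- check_binary_y(y, nrow(X))
  folds <- stratified_folds(y, k, seed, stratified)
  fold_scores <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- tryCatch(lrn$fit(X[tr, , drop = FALSE], y[tr]),
                    error = function(e)
                      stop("cross_validate: fold ", f, " fit failed: ",
                           conditionMessage(e)))
    sc <- lrn$score(fit, X[!tr, , drop = FALSE])
    fold_scores[f] <- roc_auc(sc, y[!tr])
  }
  structure(list(fold_scores = fold_scores,
                 mean = mean(fold_scores),
                 sd = stats::sd(fold_scores),
                 fold_assignments = folds,
                 config_hash = config_hash(list(label = lrn$label, k = k)),
                 seed = seed, label = lrn$label),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]: ROC-AUC %.3f +/- %.3f over %d folds\n",
              x$label, x$mean, x$sd, length(x$fold_scores)))
  cat("  folds:", paste(sprintf("%.3f", x$fold_scores), collapse = ", "), "\n")
  invisible(x)
}

#' Seeded random hyperparameter search
#'
#' Draws `budget` independent configurations from `space`, evaluates
#' each by [cross_validate()], and returns all trials with the best (by
#' mean ROC-AUC). Each space entry is a list:
#' `list(type = "uniform", min=, max=)`,
#' `list(type = "loguniform", min=, max=)`, or
#' `list(type = "choice", values = ...)`.
#'
#' @param space named list of parameter descriptions.
#' @param budget number of trials (>= 1).
#' @param make_learner function(params) returning a [learner()].
#' @param X,y data and labels.
#' @param k folds per trial.
#' @param seed integer seed; fixes the whole trial sequence.
#' @return a `search_result`: `trials` (params + cv_report each) and
#'   `best`.
#' @export
random_search <- function(space, budget, make_learner, X, y, k = 5L,
                          seed = 1L) {
  if (length(space) == 0) stop("random_search: empty search space")
  if (budget < 1) stop("random_search: budget must be >= 1")
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i) {
    lapply(space, function(sp) {
      switch(sp$type,
        uniform = stats::runif(1, sp$min, sp$max),
        loguniform = exp(stats::runif(1, log(sp$min), log(sp$max))),
        choice = sp$values[[sample.int(length(sp$values), 1)]],
        stop("random_search: unknown space type ", sp$type))
    })
  })
  trials <- vector("list", budget)
  for (i in seq_len(budget)) {
    lrn <- make_learner(draws[[i]])
    rep <- cross_validate(lrn, X, y, k = k, seed = seed + i)
    trials[[i]] <- list(params = draws[[i]], report = rep)
  }
  means <- vapply(trials, function(t) t$report$mean, 0)
  structure(list(trials = trials, best = trials[[which.max(means)]]),
            class = "search_result")
}

#' Rank features by dataset-level importance
#'
#' Sorts features by decreasing mean aggregate importance, ties broken
#' by original order (stable). The full ranking is retained; `top_k`
#' only truncates the returned table.
#'
#' @param iv an `importance_vector` (see [aggregate_importance()]).
#' @param top_k optional number of rows to return; clamped with a
#'   warning when it exceeds the feature count.
#' @param path optional file; when given, the full ranked list is
#'   written as a two-column tab-separated table (feature_id,
#'   importance) suitable as an ordered gene list for enrichment tools.
#' @return data.frame with columns `feature_id`, `importance`, ordered.
#' @export
export_importances <- function(iv, top_k = NULL, path = NULL) {
  stopifnot(inherits(iv, "importance_vector"))
  ord <- order(-iv$mean, seq_along(iv$mean))
  tab <- data.frame(feature_id = iv$feature_ids[ord],
                    importance = unname(iv$mean[ord]),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(top_k)) {
    if (top_k > nrow(tab)) {
      warning("export_importances: top_k exceeds feature count; clamped")
      top_k <- nrow(tab)
    }
    tab <- tab[seq_len(top_k), , drop = FALSE]
  }
  tab
}
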