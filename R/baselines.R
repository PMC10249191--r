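#' Specify a supervised baseline
#'
#' The classical comparators, behind one uniform fit/score contract:
#' \describe{
#'   \item{logistic}{L2-penalized logistic regression; `inv_reg` is the
#'     inverse regularisation strength (default 0.001, a strong
#'     penalty).}
#'   \item{feedforward}{multi-layer perceptron with ReLU hidden layers
#'     (default sizes 64, 32, 128, 64), trained with Adam, binary
#'     cross-entropy, and early stopping on a 20% validation split.}
#'   \item{knn}{k-nearest neighbours, uniform weights, `k = 25`.}
#'   \item{boosted_trees}{gradient-boosted trees, 120 estimators of
#'     maximum depth 3.}
#'   \item{cyclic_additive}{a round-robin boosted generalized additive
#'     model: single-feature piecewise-constant learners on binned
#'     features (max 3 leaves, max 40 bins), boosted cyclically at a
#'     low learning rate.}
#' }
#'
#' @param family one of `"logistic"`, `"feedforward"`, `"knn"`,
#'   `"boosted_trees"`, `"cyclic_additive"`.
#' @param ... family-specific hyperparameters overriding the defaults
#'   above; unrecognized names are an error.
#' @param seed integer seed.
#' @return a `baseline_spec`.
#' @export
baseline_spec <- function(family = c("logistic", "feedforward", "knn",
                                     "boosted_trees", "cyclic_additive"),
                          ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic = list(inv_reg = 0.001),
    feedforward = list(hidden = c(64L, 32L, 128L, 64L), lr = 0.01,
                       max_epochs = 200L, patience = 15L,
                       val_fraction = 0.2, batch_size = 64L),
    knn = list(k = 25L),
    boosted_trees = list(nrounds = 120L, max_depth = 3L, eta = 0.3),
    cyclic_additive = list(max_leaves = 3L, max_bins = 40L,
                           n_cycles = 60L, learning_rate = 0.05))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop("baseline_spec: unrecognized hyperparameter(s) for ", family,
         ": ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(list(family = family, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

#' Fit a baseline model
#'
#' @param spec a [baseline_spec()].
#' @param X samples x features matrix.
#' @param y binary labels (0/1).
#' @return a `fitted_baseline` usable with [score()].
#' @export
fit_baseline <- function(spec, X, y) {
  stopifnot(inherits(spec, "baseline_spec"))
  y <- check_binary_y(y, nrow(X))
  if (min(table(y)) < 2)
    stop("fit_baseline: each class needs at least 2 samples")
  x <- if (inherits(X, "OmicsMatrix")) as_plain(X) else as.matrix(X)
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    logistic = {
      std <- fit_standardizer(x)
      lam <- 1 / (nrow(x) * hp$inv_reg)
      m <- glmnet::glmnet(scale(x, std$center, std$scale), y,
                          family = "binomial", alpha = 0,
                          lambda = c(lam * 10, lam), standardize = FALSE)
      list(model = m, std = std, lambda = lam)
    },
    feedforward = mlp_fit(x, y, hp, spec$seed),
    knn = {
      if (hp$k > nrow(x))
        stop("fit_baseline: knn k (", hp$k, ") exceeds training size (",
             nrow(x), ")")
      std <- fit_standardizer(x)
      list(train = scale(x, std$center, std$scale), y = y, std = std,
           k = hp$k)
    },
    boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y)
      m <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
      list(model = m)
    },
    cyclic_additive = ebm_fit(x, y, hp))
  structure(list(family = spec$family, spec = spec, fit = fit,
                 feature_ids = colnames(x)),
            class = "fitted_baseline")
}

#' Score samples with a fitted baseline
#'
#' @param model a `fitted_baseline`.
#' @param X samples x features matrix with the fitting feature schema.
#' @return numeric vector of deceased-class scores in `[0, 1]`.
#' @export
score <- function(model, X) {
  stopifnot(inherits(model, "fitted_baseline"))
  x <- if (inherits(X, "OmicsMatrix")) as_plain(X) else as.matrix(X)
  if (!identical(colnames(x), model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(x)))
      stop("score: feature schema does not match the fitted model")
    x <- x[, model$feature_ids, drop = FALSE]
  }
  f <- model$fit
  switch(model$family,
    logistic = as.numeric(stats::predict(
      f$model, scale(x, f$std$center, f$std$scale),
      s = f$lambda, type = "response")),
    feedforward = mlp_score(f, x),
    knn = {
      pr <- class::knn(f$train, scale(x, f$std$center, f$std$scale),
                       factor(f$y, levels = c(0, 1)), k = f$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    boosted_trees = as.numeric(stats::predict(f$model,
                                              xgboost::xgb.DMatrix(x))),
    cyclic_additive = ebm_score(f, x))
}

# ---- feedforward MLP on the autodiff tape -----------------------------

mlp_fit <- function(x, y, hp, seed) {
  std <- fit_standardizer(x)
  xs <- scale(x, std$center, std$scale)
  dims <- c(ncol(xs), hp$hidden, 1L)
  set.seed(seed)
  params <- list()
  for (l in seq_len(length(dims) - 1)) {
    params[[paste0("W", l)]] <- glorot(dims[l], dims[l + 1])
    params[[paste0("b", l)]] <- matrix(0, 1, dims[l + 1])
  }
  nlayer <- length(dims) - 1
  val_idx <- stratified_holdout(y, hp$val_fraction, seed + 1L)
  tr_idx <- setdiff(seq_len(nrow(xs)), val_idx)
  opt <- adam_new(params, lr = hp$lr)
  best <- list(auc = -Inf, params = params)
  stall <- 0
  for (epoch in seq_len(hp$max_epochs)) {
    perm <- sample(tr_idx)
    for (s in seq(1, length(perm), by = hp$batch_size)) {
      idx <- perm[s:min(s + hp$batch_size - 1, length(perm))]
      if (length(idx) < 2) next
      tape <- tape_new()
      pn <- params_to_tape(tape, params)
      h <- ad_leaf(tape, xs[idx, , drop = FALSE])
      for (l in seq_len(nlayer)) {
        h <- ad_add_bias(ad_mm(h, pn[[paste0("W", l)]]),
                         pn[[paste0("b", l)]])
        if (l < nlayer) h <- ad_relu(h)
      }
      loss <- ad_bce_logits(h, y[idx])
      grads <- backward(tape, loss)
      st <- adam_step(opt, params, collect_param_grads(grads, pn))
      opt <- st$opt; params <- st$params
    }
    val_auc <- roc_auc(mlp_forward(params, nlayer, xs[val_idx, , drop = FALSE]),
                       y[val_idx])
    if (val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, params = params); stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= hp$patience) break
    }
  }
  list(params = best$params, nlayer = nlayer, std = std)
}

mlp_forward <- function(params, nlayer, xs) {
  h <- xs
  for (l in seq_len(nlayer)) {
    h <- sweep(h %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], `+`)
    if (l < nlayer) h <- pmax(h, 0)
  }
  drop(1 / (1 + exp(-h)))
}

mlp_score <- function(f, x) {
  mlp_forward(f$params, f$nlayer, scale(x, f$std$center, f$std$scale))
}

# ---- cyclic additive boosting (EBM-style) -----------------------------
#
# Round-robin gradient boosting with log-loss: each cycle visits every
# feature once and fits a piecewise-constant function on its bins with
# at most max_leaves segments (greedy split search), applied at a low
# learning rate. Newton leaf values: sum(residual) / sum(p(1-p)).

ebm_fit <- function(x, y, hp) {
  n <- nrow(x); p <- ncol(x)
  bins <- vector("list", p)
  binned <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    qs <- unique(stats::quantile(x[, j],
                                 probs = seq(0, 1, length.out = hp$max_bins + 1),
                                 type = 7, names = FALSE))
    edges <- qs[-c(1, length(qs))]
    bins[[j]] <- edges
    binned[, j] <- findInterval(x[, j], edges) + 1L
  }
  nb <- vapply(bins, function(e) length(e) + 1L, 0L)
  contrib <- lapply(seq_len(p), function(j) numeric(nb[j]))
  f0 <- log((sum(y) + 0.5) / (sum(1 - y) + 0.5))
  fx <- rep(f0, n)
  for (cycle in seq_len(hp$n_cycles)) {
    for (j in seq_len(p)) {
      if (nb[j] < 2) next
      prob <- 1 / (1 + exp(-fx))
      r <- y - prob
      w <- pmax(prob * (1 - prob), 1e-6)
      rs <- tapply(r, factor(binned[, j], levels = seq_len(nb[j])), sum,
                   default = 0)
      ws <- tapply(w, factor(binned[, j], levels = seq_len(nb[j])), sum,
                   default = 0)
      segs <- greedy_segments(as.numeric(rs), as.numeric(ws), hp$max_leaves)
      upd <- numeric(nb[j])
      for (sg in segs) {
        val <- sum(rs[sg]) / max(sum(ws[sg]), 1e-6)
        upd[sg] <- hp$learning_rate * val
      }
      contrib[[j]] <- contrib[[j]] + upd
      fx <- fx + upd[binned[, j]]
    }
  }
  list(bins = bins, contrib = contrib, f0 = f0)
}

# greedy 1-D segmentation: repeatedly apply the best single split until
# max_leaves segments (or no gain); returns a list of index vectors
greedy_segments <- function(rs, ws, max_leaves) {
  segs <- list(seq_along(rs))
  gain_of <- function(idx) {
    tot <- sum(rs[idx])^2 / max(sum(ws[idx]), 1e-6)
    best <- list(gain = 0, at = NA)
    if (length(idx) < 2) return(best)
    cr <- cumsum(rs[idx]); cw <- cumsum(ws[idx])
    nr <- length(idx)
    lg <- cr[-nr]^2 / pmax(cw[-nr], 1e-6) +
      (cr[nr] - cr[-nr])^2 / pmax(cw[nr] - cw[-nr], 1e-6) - tot
    at <- which.max(lg)
    if (lg[at] > 1e-12) best <- list(gain = lg[at], at = at)
    best
  }
  while (length(segs) < max_leaves) {
    gains <- lapply(segs, gain_of)
    gvals <- vapply(gains, `[[`, 0, "gain")
    if (all(gvals <= 0)) break
    k <- which.max(gvals)
    idx <- segs[[k]]
    at <- gains[[k]]$at
    segs <- c(segs[-k], list(idx[seq_len(at)]),
              list(idx[(at + 1):length(idx)]))
  }
  segs
}

ebm_score <- function(f, x) {
  n <- nrow(x)
  fx <- rep(f$f0, n)
  for (j in seq_along(f$bins)) {
    b <- findInterval(x[, j], f$bins[[j]]) + 1L
    fx <- fx + f$contrib[[j]][b]
  }
  1 / (1 + exp(-fx))
}
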