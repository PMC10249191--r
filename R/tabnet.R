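#' Configuration for the sequential-attention tabular network
#'
#' The model processes a feature vector in `n_steps` sequential decision
#' steps. At each step an attentive transformer produces a sparse
#' per-sample feature mask (a sparsemax projection, so each mask row is
#' a probability distribution over features); a prior, relaxed by
#' `gamma`, discourages re-using features already consumed at earlier
#' steps (`gamma = 1` forbids reuse entirely). Masked features pass
#' through a feature transformer (gated linear unit blocks, partly
#' shared across steps); the ReLU-rectified decision outputs accumulate
#' across steps into the final representation.
#'
#' @param n_steps number of decision steps (default 3).
#' @param d_decision width of the per-step decision output (default 8).
#' @param d_attention width of the attention features (default 8).
#' @param gamma prior relaxation, >= 1 (default 1.3).
#' @param shared_blocks gated-linear-unit blocks shared across steps
#'   (default 1).
#' @param step_blocks additional step-specific blocks (default 1).
#' @param mask_prob Bernoulli probability that a cell is masked (hidden
#'   and reconstructed) during self-supervised pretraining (default 0.2).
#' @param batch_size minibatch size for pretraining (default 256).
#' @param finetune_batch_size minibatch size for fine-tuning (default
#'   64; labelled cohorts are far smaller than pretraining corpora, and
#'   smaller minibatches give the optimizer enough updates per epoch).
#' @param lr Adam learning rate (default 0.02).
#' @param max_epochs training epoch cap (default 100).
#' @param patience epochs without improvement before early stopping
#'   (default 10); the learning rate is halved after `ceiling(patience/2)`
#'   stalled epochs (plateau schedule).
#' @param encoder_lr_scale learning-rate multiplier applied to the
#'   encoder (non-head) parameters when fine-tuning starts from
#'   pretrained weights (discriminative fine-tuning: the fresh
#'   classifier head learns at the full rate while the pretrained
#'   representation changes more slowly). Default 1, i.e. disabled, so
#'   pretrained and cold-start fine-tuning differ only in their
#'   initialization. Cold-start training always ignores it.
#' @param weight_decay L2 penalty coefficient (default 0).
#' @param val_fraction validation fraction held out during fine-tuning
#'   (default 0.2).
#' @param seed integer seed controlling initialization and batch order;
#'   identical configuration and data give identical weights.
#' @return an `ssl_config` list.
#' @export
ssl_config <- function(n_steps = 3L, d_decision = 8L, d_attention = 8L,
                       gamma = 1.3, shared_blocks = 1L, step_blocks = 1L,
                       mask_prob = 0.2, batch_size = 256L,
                       finetune_batch_size = 64L, lr = 0.02,
                       encoder_lr_scale = 1,
                       max_epochs = 100L, patience = 10L,
                       weight_decay = 0, val_fraction = 0.2, seed = 1L) {
  if (n_steps < 1) stop("ssl_config: n_steps must be >= 1")
  if (gamma < 1) stop("ssl_config: gamma must be >= 1")
  if (mask_prob <= 0 || mask_prob >= 1)
    stop("ssl_config: mask_prob must be in (0, 1)")
  structure(list(n_steps = as.integer(n_steps),
                 d_decision = as.integer(d_decision),
                 d_attention = as.integer(d_attention),
                 gamma = gamma,
                 shared_blocks = as.integer(shared_blocks),
                 step_blocks = as.integer(step_blocks),
                 mask_prob = mask_prob,
                 batch_size = as.integer(batch_size),
                 finetune_batch_size = as.integer(finetune_batch_size),
                 lr = lr, encoder_lr_scale = encoder_lr_scale,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "ssl_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# parameter initialization; `D` is the input feature count
tabnet_init_params <- function(cfg, D) {
  h <- cfg$d_decision + cfg$d_attention
  p <- list()
  add_glu <- function(p, name, nin, nout) {
    p[[paste0(name, "_W1")]] <- glorot(nin, nout)
    p[[paste0(name, "_b1")]] <- matrix(0, 1, nout)
    p[[paste0(name, "_W2")]] <- glorot(nin, nout)
    p[[paste0(name, "_b2")]] <- matrix(0, 1, nout)
    p
  }
  for (l in seq_len(cfg$shared_blocks))
    p <- add_glu(p, paste0("shared", l), if (l == 1) D else h, h)
  for (i in 0:cfg$n_steps)
    for (l in seq_len(cfg$step_blocks))
      p <- add_glu(p, paste0("step", i, "_", l),
                   if (cfg$shared_blocks == 0 && l == 1) D else h, h)
  for (i in seq_len(cfg$n_steps)) {
    p[[paste0("att", i, "_W")]] <- glorot(cfg$d_attention, D)
    p[[paste0("att", i, "_b")]] <- matrix(0, 1, D)
  }
  # decoder (pretraining) and classifier head (fine-tuning)
  p <- add_glu(p, "dec", cfg$d_decision, h)
  p[["rec_W"]] <- glorot(h, D)
  p[["rec_b"]] <- matrix(0, 1, D)
  p[["out_W"]] <- glorot(cfg$d_decision, 1)
  p[["out_b"]] <- matrix(0, 1, 1)
  p
}

# wrap every parameter as a tape leaf; returns nodes + name->id map
params_to_tape <- function(tape, params) {
  nodes <- lapply(params, function(v) ad_leaf(tape, v))
  nodes
}

#' One step of the attentive transformer
#'
#' Computes a decision step's sparse feature mask from the previous
#' step's attention features and the running prior:
#' `M = sparsemax(prior * (a W + b))`, then relaxes the prior to
#' `prior * (gamma - M)`. With `gamma = 1`, a feature fully used at one
#' step (mask weight 1) has prior 0 afterwards and can never be
#' re-selected; larger `gamma` permits reuse.
#'
#' @param a attention features, B x d_attention.
#' @param prior running prior, B x D, entries in `[0, gamma^steps]`.
#' @param W attention weights, d_attention x D.
#' @param b attention bias, length D.
#' @param gamma prior relaxation, >= 1.
#' @param budget per-feature remaining attention capacity in `[0, 1]`
#'   (B x D); defaults to the prior clipped into `[0, 1]`. The mask is
#'   capped elementwise by this capacity, so a spent feature
#'   (capacity 0) can never be re-selected.
#' @return list with `mask` (B x D, rows sum to 1), `prior` (the
#'   relaxed prior for the next step) and `budget` (capacity left
#'   after this step).
#' @export
attentive_mask <- function(a, prior, W, b, gamma = 1.3, budget = NULL) {
  if (ncol(a) != nrow(W))
    stop("attentive_mask: attention width does not match W")
  if (!all(dim(prior) == c(nrow(a), ncol(W))))
    stop("attentive_mask: prior must be B x D")
  if (is.null(budget)) budget <- pmin(pmax(prior, 0), 1)
  z <- sweep(a %*% W, 2, b, `+`)
  m <- capped_sparsemax(prior * z, budget)
  list(mask = m, prior = prior * (gamma - m),
       budget = pmin(pmax(budget + (gamma - 1) - m, 0), 1))
}

ad_glu <- function(x, pn, name) {
  lin1 <- ad_add_bias(ad_mm(x, pn[[paste0(name, "_W1")]]),
                      pn[[paste0(name, "_b1")]])
  lin2 <- ad_add_bias(ad_mm(x, pn[[paste0(name, "_W2")]]),
                      pn[[paste0(name, "_b2")]])
  ad_mul(lin1, ad_sigmoid(lin2))
}

# feature transformer: shared blocks then step-specific blocks, residual
# connections scaled by sqrt(0.5) between same-width blocks
ad_feature_transformer <- function(x, pn, cfg, step) {
  out <- NULL
  for (l in seq_len(cfg$shared_blocks)) {
    nm <- paste0("shared", l)
    out <- if (is.null(out)) ad_glu(x, pn, nm)
           else ad_mul_const(ad_add(out, ad_glu(out, pn, nm)), sqrt(0.5))
  }
  for (l in seq_len(cfg$step_blocks)) {
    nm <- paste0("step", step, "_", l)
    out <- if (is.null(out)) ad_glu(x, pn, nm)
           else ad_mul_const(ad_add(out, ad_glu(out, pn, nm)), sqrt(0.5))
  }
  out
}

# full encoder pass on the tape; X is an already-standardized constant
# matrix (for pretraining, the masked input)
tabnet_encode <- function(tape, pn, cfg, X) {
  D <- ncol(X)
  dec_idx <- seq_len(cfg$d_decision)
  att_idx <- cfg$d_decision + seq_len(cfg$d_attention)
  xin <- ad_leaf(tape, X)
  f0 <- ad_feature_transformer(xin, pn, cfg, 0)
  a <- ad_slice_cols(f0, att_idx)
  prior <- ad_leaf(tape, matrix(1, nrow(X), D))
  cum <- matrix(0, nrow(X), D)      # cumulative mask, for capacity caps
  dsum <- NULL
  masks <- vector("list", cfg$n_steps)
  etas <- vector("list", cfg$n_steps)
  for (i in seq_len(cfg$n_steps)) {
    z <- ad_add_bias(ad_mm(a, pn[[paste0("att", i, "_W")]]),
                     pn[[paste0("att", i, "_b")]])
    budget <- pmin(pmax(1 + (i - 1) * (cfg$gamma - 1) - cum, 0), 1)
    m <- ad_capped_sparsemax(ad_mul(prior, z), budget)
    if (!all(is.finite(ad_value(m))))
      stop("tabnet_encode: non-finite activations at decision step ", i)
    cum <- cum + ad_value(m)
    prior <- ad_mul(prior, ad_const_sub(cfg$gamma, m))
    fi <- ad_feature_transformer(ad_mul(m, xin), pn, cfg, i)
    d <- ad_relu(ad_slice_cols(fi, dec_idx))
    a <- ad_slice_cols(fi, att_idx)
    dsum <- if (is.null(dsum)) d else ad_add(dsum, d)
    masks[[i]] <- ad_value(m)
    etas[[i]] <- rowSums(ad_value(d))
  }
  list(dsum = dsum, masks = masks, etas = etas)
}

collect_param_grads <- function(grads, pnodes) {
  out <- lapply(pnodes, function(nd) grads[[nd$id]])
  out
}

#' Run the encoder and return decision output, step masks and embedding
#'
#' Exposes the forward pass of a (pre)trained model: the accumulated
#' decision output, the per-step sparse feature masks with their
#' per-sample step weights (`eta`, the ReLU-derived row sums of each
#' step's decision output), and the embedding (identical to the decision
#' output; it is what both the decoder and the classifier head consume).
#'
#' @param X samples x features matrix with the model's feature IDs.
#' @param model an `ssl_model` from [pretrain()], [finetune()] or
#'   [tabnet_new()].
#' @return list with `decision_output`, `step_masks` (list: `masks`,
#'   `etas`), and `embedding`.
#' @export
encoder_forward <- function(X, model) {
  x <- standardize_for_model(model, X)
  tape <- tape_new()
  pn <- params_to_tape(tape, model$params)
  enc <- tabnet_encode(tape, pn, model$config, x)
  list(decision_output = ad_value(enc$dsum),
       step_masks = list(masks = enc$masks, etas = enc$etas),
       embedding = ad_value(enc$dsum))
}

#' Masked-feature reconstruction loss
#'
#' The self-supervised objective: the sum over samples b and features j
#' of the squared, mask-gated, per-feature-normalized residual
#' `((fhat - f) * S / sqrt(sum_b (f - mean_b f)^2))^2`. Only cells with
#' `S = 1` (masked, to be reconstructed) contribute. Features never
#' masked in the batch contribute zero; a feature that is masked but
#' constant across the batch has an undefined normalizer and is an
#' error.
#'
#' @param batch list with `f` (true features, B x D), `fhat`
#'   (reconstruction, B x D), `S` (binary mask, B x D; 1 = masked).
#' @return scalar loss.
#' @export
reconstruction_loss <- function(batch) {
  f <- batch$f; fhat <- batch$fhat; S <- batch$S
  stopifnot(all(dim(f) == dim(fhat)), all(dim(f) == dim(S)))
  if (!all(S %in% c(0, 1))) stop("reconstruction_loss: S must be binary")
  dev2 <- colSums(sweep(f, 2, colMeans(f))^2)
  masked_cols <- colSums(S) > 0
  bad <- masked_cols & dev2 == 0
  if (any(bad))
    stop("reconstruction_loss: zero batch standard deviation for masked ",
         "feature(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  r <- (fhat - f) * S
  use <- which(masked_cols)
  sum(sweep(r[, use, drop = FALSE]^2, 2, dev2[use], `/`))
}

standardize_for_model <- function(model, X) {
  x <- if (inherits(X, "OmicsMatrix")) as_plain(X) else as.matrix(X)
  if (!is.null(model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(x)))
      stop("feature IDs do not match the model's training features")
    x <- x[, model$feature_ids, drop = FALSE]
  }
  scale(x, model$center, model$scale)
}

#' Create an untrained model (cold start)
#'
#' Initializes weights for the given feature set without any
#' pretraining; standardization statistics are taken from `X`.
#'
#' @param X samples x features matrix the model will be trained on.
#' @param config an [ssl_config()].
#' @return an `ssl_model` with `pretrained = FALSE`.
#' @export
tabnet_new <- function(X, config = ssl_config()) {
  x <- if (inherits(X, "OmicsMatrix")) as_plain(X) else as.matrix(X)
  std <- fit_standardizer(x)
  set.seed(config$seed)
  structure(list(params = tabnet_init_params(config, ncol(x)),
                 config = config,
                 feature_ids = colnames(x),
                 center = std$center, scale = std$scale,
                 pretrained = FALSE, finetuned = FALSE,
                 history = list()),
            class = "ssl_model")
}

#' @export
print.ssl_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("ssl_model: %d features, %d steps, d_decision %d, ",
                     "gamma %.2f\n  pretrained: %s, fine-tuned: %s\n"),
              length(x$feature_ids), cfg$n_steps, cfg$d_decision, cfg$gamma,
              x$pretrained, x$finetuned))
  invisible(x)
}

#' Self-supervised pretraining by masked-feature reconstruction
#'
#' Trains encoder and decoder on an unlabelled corpus: per minibatch, a
#' Bernoulli(`mask_prob`) binary mask hides cells (their standardized
#' values are zeroed on input), and the decoder reconstructs them under
#' the normalized masked reconstruction loss
#' ([reconstruction_loss()]). Adam with a plateau-halved learning rate
#' and early stopping on the epoch loss; the best epoch's weights are
#' kept. Features constant within a batch are silently excluded from
#' that batch's loss.
#'
#' @param corpus unlabelled samples x features matrix.
#' @param config an [ssl_config()].
#' @param verbose print per-epoch losses.
#' @return an `ssl_model` with `pretrained = TRUE`; `history$pretrain`
#'   holds the per-epoch mean loss per masked cell.
#' @export
pretrain <- function(corpus, config = ssl_config(), verbose = FALSE) {
  x <- if (inherits(corpus, "OmicsMatrix")) as_plain(corpus) else as.matrix(corpus)
  model <- tabnet_new(x, config)
  xs <- scale(x, model$center, model$scale)
  n <- nrow(xs); D <- ncol(xs)
  set.seed(config$seed + 1L)
  params <- model$params
  opt <- adam_new(params, lr = config$lr)
  best <- list(loss = Inf, params = params)
  stall <- 0
  history <- numeric(0)
  sched_patience <- max(1L, ceiling(config$patience / 2))
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    tot_loss <- 0; tot_cells <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      if (length(idx) < 2) next
      f <- xs[idx, , drop = FALSE]
      S <- matrix(stats::rbinom(length(idx) * D, 1, config$mask_prob),
                  length(idx), D)
      dev2 <- colSums(sweep(f, 2, colMeans(f))^2)
      S[, dev2 == 0] <- 0              # constant-in-batch: skip
      if (sum(S) == 0) next
      tape <- tape_new()
      pn <- params_to_tape(tape, params)
      enc <- tabnet_encode(tape, pn, config, f * (1 - S))
      g <- ad_glu(enc$dsum, pn, "dec")
      fhat <- ad_add_bias(ad_mm(g, pn$rec_W), pn$rec_b)
      denom2 <- ifelse(dev2 > 0, dev2, 1)
      loss <- ad_recon_loss(fhat, f, S, denom2)
      grads <- backward(tape, loss)
      pg <- collect_param_grads(grads, pn)
      if (config$weight_decay > 0)
        pg <- mapply(function(g0, p0) {
          if (is.null(g0)) g0 else g0 + 2 * config$weight_decay * p0
        }, pg, params, SIMPLIFY = FALSE)
      st <- adam_step(opt, params, pg)
      opt <- st$opt; params <- st$params
      tot_loss <- tot_loss + ad_value(loss)
      tot_cells <- tot_cells + sum(S)
    }
    ep_loss <- tot_loss / max(tot_cells, 1)
    history <- c(history, ep_loss)
    if (verbose) cat(sprintf("pretrain epoch %d: loss/cell %.4f (lr %.4g)\n",
                             epoch, ep_loss, opt$lr))
    if (ep_loss < best$loss - 1e-6) {
      best <- list(loss = ep_loss, params = params)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall %% sched_patience == 0) opt$lr <- opt$lr * 0.5
      if (stall >= config$patience) break
    }
  }
  if (stall >= config$patience && best$loss >= history[1])
    warning("pretrain: loss did not improve; returning best checkpoint")
  model$params <- best$params
  model$pretrained <- TRUE
  model$history$pretrain <- history
  model
}

stratified_holdout <- function(y, fraction, seed) {
  set.seed(seed)
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    nv <- max(1L, round(length(idx) * fraction))
    val <- c(val, sample(idx, nv))
  }
  sort(val)
}

#' Fine-tune a model on labelled data
#'
#' Trains the encoder plus a linear classifier head with binary
#' cross-entropy, starting from pretrained weights when the model has
#' them (otherwise from the cold-start initialization). A stratified
#' validation split drives early stopping on validation ROC-AUC and the
#' plateau learning-rate schedule; the best-validation weights are kept.
#'
#' @param model an `ssl_model` ([pretrain()] output or [tabnet_new()]).
#' @param X labelled samples x features matrix (features must match the
#'   model).
#' @param y binary labels (0/1).
#' @param config optional [ssl_config()] overriding the model's training
#'   settings (architecture fields are taken from the model).
#' @param verbose print per-epoch metrics.
#' @return an `ssl_model` with `finetuned = TRUE`; scores via
#'   [predict()][predict.ssl_model].
#' @export
finetune <- function(model, X, y, config = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ssl_model"))
  cfg <- if (is.null(config)) model$config else config
  x <- standardize_for_model(model, X)
  y <- check_binary_y(y, nrow(x))
  n <- nrow(x)
  val_idx <- stratified_holdout(y, cfg$val_fraction, cfg$seed + 2L)
  tr_idx <- setdiff(seq_len(n), val_idx)
  set.seed(cfg$seed + 3L)
  params <- model$params
  opt <- adam_new(params, lr = cfg$lr)
  # discriminative fine-tuning: pretrained encoder updates more slowly
  # than the fresh head
  lr_scale <- NULL
  esc <- cfg$encoder_lr_scale %||% 1
  if (isTRUE(model$pretrained) && esc != 1) {
    lr_scale <- as.list(stats::setNames(rep(esc, length(params)),
                                        names(params)))
    lr_scale$out_W <- 1
    lr_scale$out_b <- 1
  }
  best <- list(auc = -Inf, params = params)
  stall <- 0
  sched_patience <- max(1L, ceiling(cfg$patience / 2))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  bs <- cfg$finetune_batch_size %||% cfg$batch_size
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(tr_idx)
    starts <- seq(1, length(perm), by = bs)
    ep_loss <- 0; nb <- 0
    for (s in starts) {
      idx <- perm[s:min(s + bs - 1, length(perm))]
      if (length(idx) < 2) next
      tape <- tape_new()
      pn <- params_to_tape(tape, params)
      enc <- tabnet_encode(tape, pn, cfg, x[idx, , drop = FALSE])
      logits <- ad_add_bias(ad_mm(enc$dsum, pn$out_W), pn$out_b)
      loss <- ad_bce_logits(logits, y[idx])
      grads <- backward(tape, loss)
      pg <- collect_param_grads(grads, pn)
      if (cfg$weight_decay > 0)
        pg <- mapply(function(g0, p0) {
          if (is.null(g0)) g0 else g0 + 2 * cfg$weight_decay * p0
        }, pg, params, SIMPLIFY = FALSE)
      st <- adam_step(opt, params, pg, lr_scale)
      opt <- st$opt; params <- st$params
      ep_loss <- ep_loss + ad_value(loss); nb <- nb + 1
    }
    val_scores <- tabnet_scores(params, cfg, x[val_idx, , drop = FALSE])
    val_auc <- roc_auc(val_scores, y[val_idx])
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / max(nb, 1),
                                         val_auc = val_auc))
    if (verbose) cat(sprintf("finetune epoch %d: loss %.4f val AUC %.3f\n",
                             epoch, ep_loss / max(nb, 1), val_auc))
    if (val_auc > best$auc + 1e-6) {
      best <- list(auc = val_auc, params = params)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall %% sched_patience == 0) opt$lr <- opt$lr * 0.5
      if (stall >= cfg$patience) break
    }
  }
  model$params <- best$params
  model$config <- cfg
  model$finetuned <- TRUE
  model$history$finetune <- history
  model$val_auc <- best$auc
  model
}

# scores without building gradients for the head
tabnet_scores <- function(params, cfg, x_std) {
  tape <- tape_new()
  pn <- params_to_tape(tape, params)
  enc <- tabnet_encode(tape, pn, cfg, x_std)
  z <- ad_value(enc$dsum) %*% params$out_W
  z <- sweep(z, 2, params$out_b, `+`)
  drop(1 / (1 + exp(-z)))
}

#' Predict deceased-class probabilities
#'
#' @param object a fine-tuned `ssl_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.ssl_model <- function(object, newdata, ...) {
  if (!object$finetuned)
    warning("predict.ssl_model: model has no trained classifier head")
  x <- standardize_for_model(object, newdata)
  tabnet_scores(object$params, object$config, x)
}

#' Aggregate per-step masks into feature importances
#'
#' Combines the per-step sparse masks into a per-sample importance
#' vector: each step's mask is weighted by that sample's step weight
#' `eta` (the ReLU-derived row sum of the step's decision output) and
#' the weighted sum is normalized to a distribution over features. The
#' dataset-level importance is the mean over samples. The default
#' normalizer is the unsquared weighted mask sum, which guarantees the
#' per-sample importances sum to one; `squared_denominator = TRUE`
#' switches to the variant that squares the mask term in the normalizer
#' (importances then no longer sum to one; provided for audit).
#'
#' @param masks list as returned in `step_masks` by [encoder_forward()]:
#'   `masks` (per-step B x D matrices) and `etas` (per-step length-B
#'   weights).
#' @param feature_ids character vector of D feature IDs.
#' @param squared_denominator use the squared-mask normalizer.
#' @return an `importance_vector`: `per_sample` (B x D), `mean`
#'   (length D, named), `feature_ids`.
#' @export
aggregate_importance <- function(masks, feature_ids,
                                 squared_denominator = FALSE) {
  M <- masks$masks; etas <- masks$etas
  stopifnot(length(M) >= 1, length(M) == length(etas))
  B <- nrow(M[[1]]); D <- ncol(M[[1]])
  if (length(feature_ids) != D)
    stop("aggregate_importance: feature_ids length must equal mask width")
  num <- matrix(0, B, D)
  den_sq <- numeric(B)
  for (i in seq_along(M)) {
    num <- num + etas[[i]] * M[[i]]
    den_sq <- den_sq + rowSums(etas[[i]] * M[[i]]^2)
  }
  den <- if (squared_denominator) den_sq else rowSums(num)
  zero <- den == 0
  if (any(zero)) {
    warning("aggregate_importance: ", sum(zero),
            " sample(s) with zero total step weight; set to uniform")
    num[zero, ] <- 1 / D
    den[zero] <- if (squared_denominator) 1 else rowSums(num[zero, , drop = FALSE])
  }
  per_sample <- num / den
  colnames(per_sample) <- feature_ids
  structure(list(per_sample = per_sample,
                 mean = colMeans(per_sample),
                 feature_ids = feature_ids),
            class = "importance_vector")
}

#' Feature importances of a trained model on a dataset
#'
#' Convenience wrapper: runs [encoder_forward()] and
#' [aggregate_importance()].
#'
#' @param model a trained `ssl_model`.
#' @param X samples x features matrix.
#' @param squared_denominator see [aggregate_importance()].
#' @return an `importance_vector`.
#' @export
tabnet_explain <- function(model, X, squared_denominator = FALSE) {
  fw <- encoder_forward(X, model)
  aggregate_importance(fw$step_masks, model$feature_ids,
                       squared_denominator = squared_denominator)
}
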