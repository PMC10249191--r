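test_that("sparsemax matches the brute-force simplex projection", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(1:6, 1)
    z <- rnorm(k, sd = 3)
    expect_equal(sparsemax(z), proj_simplex_brute(z), tolerance = 1e-9)
  }
  expect_equal(sparsemax(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(sparsemax(c(10, 0, 0)), c(1, 0, 0))
  expect_error(sparsemax(numeric(0)), "empty")
  expect_error(sparsemax(c(1, NaN)), "finite")
})

test_that("sparsemax rows are distributions on random matrices", {
  set.seed(102)
  z <- matrix(rnorm(1000 * 7, sd = 2), 1000, 7)
  p <- sparsemax(z)
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 1000), tolerance = 1e-12)
})

test_that("attentive mask follows the prior arithmetic", {
  # gamma = 1: a fully used feature cannot be reused
  a <- matrix(c(1, -1), 1, 2)
  W <- matrix(c(5, 0, 0, 0), 2, 2)   # drives feature 1 hard
  b <- c(0, 0)
  prior <- matrix(1, 1, 2)
  st1 <- attentive_mask(a, prior, W, b, gamma = 1)
  expect_equal(st1$mask, matrix(c(1, 0), 1, 2))
  expect_equal(st1$prior[1, 1], 0)
  st2 <- attentive_mask(a, st1$prior, W, b, gamma = 1)
  expect_equal(st2$mask[1, 1], 0)    # feature 1 is spent
  # gamma = 2 hand trace on a 2-feature toy
  g1 <- attentive_mask(a, matrix(1, 1, 2), W, b, gamma = 2)
  expect_equal(g1$prior, matrix(1, 1, 2) * (2 - g1$mask))
  z2 <- (a %*% W + rep(b, each = 1)) * g1$prior
  expect_equal(attentive_mask(a, g1$prior, W, b, 2)$mask,
               sparsemax(z2))
  expect_error(attentive_mask(a, matrix(1, 2, 2), W, b), "B x D")
})

test_that("reconstruction loss equals the three-loop oracle", {
  set.seed(103)
  for (i in 1:100) {
    B <- sample(2:6, 1); D <- sample(1:5, 1)
    f <- matrix(rnorm(B * D), B, D)
    fhat <- matrix(rnorm(B * D), B, D)
    S <- matrix(rbinom(B * D, 1, 0.5), B, D)
    expect_equal(reconstruction_loss(list(f = f, fhat = fhat, S = S)),
                 naive_recon_loss(f, fhat, S), tolerance = 1e-6)
  }
  # hand example: B=2, D=1, f=(0,2), fhat=(1,1), S=1 -> loss 1
  expect_equal(reconstruction_loss(list(f = matrix(c(0, 2), 2, 1),
                                        fhat = matrix(1, 2, 1),
                                        S = matrix(1, 2, 1))), 1)
  # perfect reconstruction and empty mask give zero
  f <- matrix(rnorm(6), 3, 2)
  expect_equal(reconstruction_loss(list(f = f, fhat = f,
                                        S = matrix(1, 3, 2))), 0)
  expect_equal(reconstruction_loss(list(f = f, fhat = f + 1,
                                        S = matrix(0, 3, 2))), 0)
  # masked constant feature errors
  fc <- cbind(c(1, 1, 1), rnorm(3))
  expect_error(reconstruction_loss(list(f = fc, fhat = fc,
                                        S = matrix(1, 3, 2))), "standard deviation")
})

test_that("analytic gradients match finite differences", {
  tv <- asNamespace("tabvital")
  set.seed(104)
  cfg <- ssl_config(n_steps = 2, d_decision = 3, d_attention = 3,
                    shared_blocks = 1, step_blocks = 1, seed = 104)
  D <- 5; B <- 6
  X <- matrix(rnorm(B * D), B, D)
  y <- c(1, 0, 1, 0, 1, 0)
  params <- tv$tabnet_init_params(cfg, D)
  loss_fn <- function(params) {
    tape <- tv$tape_new()
    pn <- tv$params_to_tape(tape, params)
    enc <- tv$tabnet_encode(tape, pn, cfg, X)
    logits <- tv$ad_add_bias(tv$ad_mm(enc$dsum, pn$out_W), pn$out_b)
    loss <- tv$ad_bce_logits(logits, y)
    list(val = tv$ad_value(loss), tape = tape, loss = loss, pn = pn)
  }
  r <- loss_fn(params)
  pg <- tv$collect_param_grads(tv$backward(r$tape, r$loss), r$pn)
  eps <- 1e-6
  for (nm in c("shared1_W1", "step0_1_W2", "step1_1_W1", "step2_1_b1",
               "att1_W", "att2_b", "out_W")) {
    g <- pg[[nm]]
    expect_false(is.null(g))
    for (ii in unique(c(1, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (loss_fn(p2)$val - loss_fn(p3)$val) / (2 * eps)
      expect_equal(unname(g[ii]), num, tolerance = 1e-3)
    }
  }
})

test_that("encoder masks are distributions and respect gamma = 1 budgets", {
  set.seed(105)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("P%02d", 1:40), sprintf("F%d", 1:6)))
  cfg <- ssl_config(n_steps = 3, gamma = 1, seed = 105)
  model <- tabnet_new(X, cfg)
  fw <- encoder_forward(X, model)
  cum <- Reduce(`+`, fw$step_masks$masks)
  for (m in fw$step_masks$masks) {
    expect_true(all(m >= -1e-12))
    expect_equal(unname(rowSums(m)), rep(1, 40), tolerance = 1e-9)
  }
  # with gamma = 1 no feature's cumulative mask can exceed 1
  expect_true(all(cum <= 1 + 1e-9))
  expect_true(all(vapply(fw$step_masks$etas, function(e) all(e >= 0), TRUE)))
})

test_that("aggregate importance matches hand evaluation and normalizes", {
  # two steps, D = 3, hand-set masks and etas
  m1 <- matrix(c(0.5, 0.5, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  m2 <- matrix(c(0, 0, 1, 0, 0.5, 0.5), 2, 3, byrow = TRUE)
  etas <- list(c(2, 1), c(1, 3))
  iv <- aggregate_importance(list(masks = list(m1, m2), etas = etas),
                             c("a", "b", "c"))
  hand1 <- (2 * m1[1, ] + 1 * m2[1, ]) / 3
  hand2 <- (1 * m1[2, ] + 3 * m2[2, ]) / 4
  expect_equal(unname(iv$per_sample[1, ]), hand1)
  expect_equal(unname(iv$per_sample[2, ]), hand2)
  expect_equal(unname(rowSums(iv$per_sample)), c(1, 1))
  expect_equal(sum(iv$mean), 1)
  # single step with eta 1: importance equals the mask rows
  iv1 <- aggregate_importance(list(masks = list(m1), etas = list(c(1, 1))),
                              c("a", "b", "c"))
  expect_equal(unclass(iv1$per_sample), m1, ignore_attr = TRUE)
  # zero total weight falls back to uniform with a warning
  expect_warning(
    iv0 <- aggregate_importance(list(masks = list(m1), etas = list(c(0, 1))),
                                c("a", "b", "c")),
    "uniform")
  expect_equal(unname(iv0$per_sample[1, ]), rep(1 / 3, 3))
})

test_that("pretraining is deterministic and learns correlated structure", {
  set.seed(106)
  n <- 600; D <- 20
  z <- matrix(rnorm(n * 2), n, 2)
  L <- matrix(rnorm(2 * D), 2, D)
  X <- z %*% L + 0.3 * matrix(rnorm(n * D), n, D)
  dimnames(X) <- list(sprintf("S%03d", 1:n), sprintf("F%02d", 1:D))
  cfg <- ssl_config(seed = 42, max_epochs = 25, patience = 6,
                    batch_size = 128)
  a <- pretrain(X, cfg)
  b <- pretrain(X, cfg)
  expect_identical(a$params, b$params)
  h <- a$history$pretrain
  expect_gt(h[1] / min(h), 2)   # loss at least halves on correlated data
})

test_that("pure-noise pretraining plateaus at the unpredictable baseline", {
  set.seed(107)
  X <- matrix(rnorm(600 * 15), 600, 15,
              dimnames = list(sprintf("S%03d", 1:600), sprintf("F%02d", 1:15)))
  cfg <- ssl_config(seed = 7, max_epochs = 10, patience = 4,
                    batch_size = 150)
  # no structure to exploit: improvement may stall, which is reported
  suppressWarnings(m <- pretrain(X, cfg))
  h <- m$history$pretrain
  # per masked cell the normalized residual cannot beat ~1/B for noise
  expect_gt(min(h), 0.5 / 150)
  expect_lt(min(h), 2 / 150)
})

test_that("fine-tuning separates a separable toy and is null on noise", {
  set.seed(108)
  y <- rep(c(0L, 1L), each = 60)
  X <- cbind(f1 = y * 2 + rnorm(120, sd = 0.1), f2 = rnorm(120))
  rownames(X) <- sprintf("P%03d", 1:120)
  cfg <- ssl_config(seed = 3, max_epochs = 30, patience = 8)
  m <- finetune(tabnet_new(X, cfg), X, y)
  expect_equal(m$val_auc, 1.0)
  expect_true(all(predict(m, X) >= 0 & predict(m, X) <= 1))
  # permuted labels: chance-level validation AUC
  set.seed(109)
  Xn <- matrix(rnorm(200 * 8), 200, 8,
               dimnames = list(sprintf("P%03d", 1:200), sprintf("F%d", 1:8)))
  yn <- rbinom(200, 1, 0.3)
  mn <- finetune(tabnet_new(Xn, ssl_config(seed = 2, max_epochs = 15,
                                           patience = 5)), Xn, yn)
  expect_lt(abs(mn$val_auc - 0.5), 0.25)
  expect_error(finetune(tabnet_new(Xn, cfg), Xn, rep(1, 200)), "class")
})

test_that("a planted dominant feature earns top importance", {
  set.seed(110)
  y <- rep(c(0L, 1L), each = 80)
  X <- cbind(sig = y * 3 + rnorm(160, sd = 0.3),
             matrix(rnorm(160 * 5), 160, 5))
  colnames(X) <- c("sig", sprintf("n%d", 1:5))
  rownames(X) <- sprintf("P%03d", 1:160)
  cfg <- ssl_config(seed = 4, max_epochs = 30, patience = 8)
  m <- finetune(tabnet_new(X, cfg), X, y)
  iv <- tabnet_explain(m, X)
  expect_identical(export_importances(iv)$feature_id[1], "sig")
})
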