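# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape is an environment accumulating nodes in topological order; each
# node stores its value, its parent node ids, and one vector-Jacobian
# product closure per parent. backward() seeds the terminal node with 1
# and sweeps the tape in reverse. Only the operations the sequential-
# attention network needs are implemented; each op's vjp is verified
# against central finite differences in the test suite.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$vals <- list()
  t$parents <- list()
  t$vjps <- list()
  t$n <- 0L
  t
}

ad_push <- function(tape, value, parents = integer(0), vjps = list()) {
  # force arguments before claiming an id: nested op calls inside an
  # argument expression must allocate their nodes first, or a child
  # could end up with a smaller id than its parent and the reverse
  # sweep would miss it
  force(value); force(parents); force(vjps)
  tape$n <- tape$n + 1L
  id <- tape$n
  tape$vals[[id]] <- value
  tape$parents[[id]] <- parents
  tape$vjps[[id]] <- vjps
  list(id = id, tape = tape)
}

ad_value <- function(x) x$tape$vals[[x$id]]

# leaf (parameter or input); constants need no node at all
ad_leaf <- function(tape, value) ad_push(tape, value)

ad_mm <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A %*% B, c(a$id, b$id),
          list(function(g) g %*% t(B), function(g) t(A) %*% g))
}

ad_add <- function(a, b) {
  ad_push(a$tape, ad_value(a) + ad_value(b), c(a$id, b$id),
          list(function(g) g, function(g) g))
}

# matrix + per-column bias vector (row-broadcast)
ad_add_bias <- function(a, b) {
  A <- ad_value(a); bv <- ad_value(b)
  ad_push(a$tape, sweep(A, 2, bv, `+`), c(a$id, b$id),
          list(function(g) g, function(g) colSums(g)))
}

ad_sub <- function(a, b) {
  ad_push(a$tape, ad_value(a) - ad_value(b), c(a$id, b$id),
          list(function(g) g, function(g) -g))
}

ad_mul <- function(a, b) {
  A <- ad_value(a); B <- ad_value(b)
  ad_push(a$tape, A * B, c(a$id, b$id),
          list(function(g) g * B, function(g) g * A))
}

# elementwise product with a constant matrix/scalar
ad_mul_const <- function(a, k) {
  ad_push(a$tape, ad_value(a) * k, a$id, list(function(g) g * k))
}

ad_add_const <- function(a, k) {
  ad_push(a$tape, ad_value(a) + k, a$id, list(function(g) g))
}

# k - A for scalar constant k
ad_const_sub <- function(k, a) {
  ad_push(a$tape, k - ad_value(a), a$id, list(function(g) -g))
}

ad_relu <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, pmax(A, 0), a$id, list(function(g) g * (A > 0)))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ad_value(a)))
  ad_push(a$tape, s, a$id, list(function(g) g * s * (1 - s)))
}

ad_slice_cols <- function(a, idx) {
  A <- ad_value(a)
  nc <- ncol(A)
  ad_push(a$tape, A[, idx, drop = FALSE], a$id,
          list(function(g) {
            out <- matrix(0, nrow(g), nc)
            out[, idx] <- g
            out
          }))
}

ad_rowsums <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, matrix(rowSums(A), ncol = 1), a$id,
          list(function(g) matrix(g, nrow(A), ncol(A))))
}

#' Sparsemax: Euclidean projection of each row onto the probability simplex
#'
#' The sparse analogue of softmax used by the attentive transformer:
#' each row of `z` is projected onto the simplex, yielding non-negative
#' weights that sum to one, usually with exact zeros. Computed by the
#' sorted-threshold algorithm: with the row sorted decreasingly, the
#' support size is the largest k with `1 + k*z_(k) > sum_{j<=k} z_(j)`,
#' the threshold is `tau = (sum of the top-k values - 1)/k`, and the
#' output is `max(z - tau, 0)`.
#'
#' @param z numeric vector or matrix (rows are projected independently).
#' @return object of the same shape; each row non-negative, summing to 1.
#' @export
sparsemax <- function(z) {
  vec <- is.null(dim(z))
  if (vec) {
    if (length(z) == 0) stop("sparsemax: empty input")
    z <- matrix(z, nrow = 1)
  }
  if (!all(is.finite(z))) stop("sparsemax: non-finite entries")
  k <- ncol(z)
  zs <- t(apply(z, 1, sort, decreasing = TRUE))
  if (k == 1) zs <- matrix(zs, ncol = 1)
  cs <- t(apply(zs, 1, cumsum))
  if (k == 1) cs <- matrix(cs, ncol = 1)
  supp <- sweep(zs * rep(seq_len(k), each = nrow(z)), 2, rep(1, k), `+`) > cs
  ksupp <- rowSums(supp)
  tau <- (cs[cbind(seq_len(nrow(z)), ksupp)] - 1) / ksupp
  out <- pmax(z - tau, 0)
  if (vec) out <- drop(out)
  out
}

#' Sparsemax projection with per-coordinate capacity caps
#'
#' Projects each row of `v` onto `{p : sum(p) = 1, 0 <= p <= cap}` —
#' the simplex intersected with a box. Used by the attentive
#' transformer to enforce each feature's remaining attention capacity;
#' with all caps at 1 it reduces to [sparsemax()]. Rows whose total
#' capacity is below 1 (possible only when the step budget is
#' over-exhausted, e.g. more decision steps than features at gamma = 1)
#' fall back to the uncapped projection.
#'
#' @param v numeric matrix of scores (rows projected independently).
#' @param cap matrix of per-entry upper bounds in `[0, 1]`.
#' @return matrix of the same shape; rows sum to 1.
#' @export
capped_sparsemax <- function(v, cap) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (is.null(dim(cap))) cap <- matrix(cap, nrow = nrow(v),
                                       ncol = ncol(v), byrow = TRUE)
  stopifnot(all(dim(v) == dim(cap)))
  cap <- pmin(pmax(cap, 0), 1)
  tot <- rowSums(cap)
  deg <- tot < 1 - 1e-12
  out <- matrix(0, nrow(v), ncol(v))
  if (any(deg)) out[deg, ] <- sparsemax(v[deg, , drop = FALSE])
  ok <- which(!deg)
  if (length(ok)) {
    vv <- v[ok, , drop = FALSE]
    cc <- cap[ok, , drop = FALSE]
    lo <- apply(vv - cc, 1, min) - 1e-9   # all saturated: f = sum(cap) >= 1
    hi <- apply(vv, 1, max)               # all zero: f = 0
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      f <- rowSums(pmin(pmax(vv - mid, 0), cc))
      lower <- f > 1
      lo <- ifelse(lower, mid, lo)
      hi <- ifelse(lower, hi, mid)
    }
    tau <- (lo + hi) / 2
    p <- pmin(pmax(vv - tau, 0), cc)
    # exact refinement from the identified active sets
    tol <- 1e-7
    free <- p > tol & p < cc - tol
    nF <- rowSums(free)
    satc <- p >= cc - tol
    refinable <- nF > 0
    tau2 <- (rowSums(vv * free) + rowSums(cc * satc) - 1) / pmax(nF, 1)
    tau <- ifelse(refinable, tau2, tau)
    p <- pmin(pmax(vv - tau, 0), cc)
    out[ok, ] <- p
  }
  out
}

# tape op; the cap is treated as a constant (no gradient through the
# attention-capacity bookkeeping)
ad_capped_sparsemax <- function(a, cap) {
  V <- ad_value(a)
  P <- capped_sparsemax(V, cap)
  capm <- pmin(pmax(if (is.null(dim(cap))) matrix(cap, nrow(V), ncol(V),
                                                  byrow = TRUE) else cap,
                    0), 1)
  tol <- 1e-7
  FR <- P > tol & P < capm - tol      # free set: interior coordinates
  ad_push(a$tape, P, a$id,
          list(function(g) {
            nf <- rowSums(FR)
            avg <- ifelse(nf > 0, rowSums(g * FR) / pmax(nf, 1), 0)
            (g - avg) * FR
          }))
}

ad_sparsemax <- function(a) {
  P <- sparsemax(ad_value(a))
  S <- P > 0
  ad_push(a$tape, P, a$id,
          list(function(g) {
            avg <- rowSums(g * S) / rowSums(S)
            (g - avg) * S
          }))
}

ad_sum <- function(a) {
  A <- ad_value(a)
  ad_push(a$tape, sum(A), a$id,
          list(function(g) array(g, dim = dim(A))))
}

# masked, per-feature-normalized squared reconstruction error; f (targets),
# S (binary mask) and denom2 (squared per-feature normalizer, length D) are
# constants -- gradient flows into the reconstruction only
ad_recon_loss <- function(fhat, f, S, denom2) {
  Fh <- ad_value(fhat)
  R <- (Fh - f) * S
  val <- sum(sweep(R^2, 2, denom2, `/`))
  ad_push(fhat$tape, val, fhat$id,
          list(function(g) g * 2 * sweep(R, 2, denom2, `/`)))
}

# numerically stable binary cross-entropy on logits, mean over the batch
ad_bce_logits <- function(z, y) {
  Z <- ad_value(z)
  B <- length(Z)
  val <- sum(pmax(Z, 0) - Z * y + log1p(exp(-abs(Z)))) / B
  s <- 1 / (1 + exp(-Z))
  ad_push(z$tape, val, z$id, list(function(g) g * (s - y) / B))
}

backward <- function(tape, loss) {
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    ps <- tape$parents[[id]]
    if (length(ps) == 0) next
    vjps <- tape$vjps[[id]]
    for (k in seq_along(ps)) {
      contrib <- vjps[[k]](g)
      p <- ps[k]
      grads[[p]] <- if (is.null(grads[[p]])) contrib else grads[[p]] + contrib
    }
  }
  grads
}

# ---- Adam optimizer ---------------------------------------------------

adam_new <- function(params, lr = 0.02, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0,
       m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))))
}

adam_step <- function(opt, params, grads, lr_scale = NULL) {
  opt$t <- opt$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - opt$beta2^opt$t)
    lr <- opt$lr * (if (is.null(lr_scale)) 1 else lr_scale[[nm]] %||% 1)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, params = params)
}
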