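# Independent oracles used across the suite; deliberately brute-force
# and separate from the implementation paths they check.

# Euclidean projection onto the simplex by KKT enumeration over all
# candidate support sets (feasible only for small k)
proj_simplex_brute <- function(z) {
  k <- length(z)
  best <- NULL
  bestd <- Inf
  for (S in 1:(2^k - 1)) {
    idx <- which(bitwAnd(S, 2^(0:(k - 1))) > 0)
    tau <- (sum(z[idx]) - 1) / length(idx)
    p <- rep(0, k)
    p[idx] <- z[idx] - tau
    if (all(p >= -1e-12) && abs(sum(p) - 1) < 1e-9) {
      d <- sum((p - z)^2)
      if (d < bestd - 1e-12) {
        bestd <- d
        best <- p
      }
    }
  }
  best
}

# ROC-AUC by enumerating every positive-negative pair, ties half credit
auc_pairs <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# masked reconstruction loss by three explicit loops
naive_recon_loss <- function(f, fhat, S) {
  B <- nrow(f); D <- ncol(f)
  tot <- 0
  for (j in seq_len(D)) {
    if (sum(S[, j]) == 0) next
    mu <- mean(f[, j])
    denom <- sqrt(sum((f[, j] - mu)^2))
    for (b in seq_len(B))
      tot <- tot + ((fhat[b, j] - f[b, j]) * S[b, j] / denom)^2
  }
  tot
}

# small labelled matrix with a planted linear signal
toy_signal_data <- function(n = 120, p = 8, n_inf = 2, d = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, seq_len(n_inf)] <- x[, seq_len(n_inf)] + d * y
  dimnames(x) <- list(sprintf("P%03d", seq_len(n)),
                      sprintf("F%02d", seq_len(p)))
  list(x = x, y = y)
}
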