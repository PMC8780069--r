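# Independent oracles and small utilities shared across the suite. These stay
# deliberately naive (loops, explicit matrices, grids) so they cannot share a
# bug with the vectorized implementation paths they check.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(a)), max(abs(b)))
}

# Triple-loop residual encoding: w_ij = softmax_j(-s_j ||x_i - d_j||^2),
# e_j = sum_i w_ij (x_i - d_j).
naive_encoding <- function(X, D, S) {
  m <- nrow(X); n <- nrow(D); c <- ncol(X)
  W <- matrix(0, m, n)
  for (i in seq_len(m)) {
    a <- numeric(n)
    for (j in seq_len(n)) a[j] <- -S[j] * sum((X[i, ] - D[j, ])^2)
    e <- exp(a - max(a))
    W[i, ] <- e / sum(e)
  }
  E <- matrix(0, n, c)
  for (j in seq_len(n)) {
    for (i in seq_len(m)) E[j, ] <- E[j, ] + W[i, j] * (X[i, ] - D[j, ])
  }
  list(W = W, E = E)
}

# Explicit full-matrix bilinear interaction: f_i = x' W_i e + b_i with
# W_i = U diag(Q[, i]) V'.
full_bilinear_oracle <- function(x, e, U, V, Q, B) {
  o <- ncol(Q); k <- ncol(U)
  out <- numeric(o)
  for (i in seq_len(o)) {
    Wi <- U %*% diag(Q[, i], k, k) %*% t(V)
    out[i] <- drop(t(x) %*% Wi %*% e) + B[i]
  }
  out
}

shrinkage_objective <- function(z, f, lambda) 0.5 * (z - f)^2 + lambda * abs(z)

# Pairwise-concordance (Mann-Whitney) AUC for a binary problem.
concordance_auc <- function(positive, scores) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

tiny_model <- function(seed = 3L, n_classes = 4L) {
  build_model(model_config("tiny", n_classes = n_classes), seed = seed)
}

small_phantoms <- function(n_per_class, n_classes = 4L, seed = 11L) {
  generate_phantoms(phantom_config(n_per_class = n_per_class,
                                   n_classes = n_classes, image_size = 56L,
                                   seed = seed))
}
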