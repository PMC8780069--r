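# Factorized bilinear encoding (FBE) fusion. A full bilinear interaction
# f_i = x' W_i e + b_i (W_i an a x b matrix per output i) costs o*(a*b + 1)
# parameters; factorizing W_i = U_i V_i' with rank k and absorbing the
# all-ones reduction into a k x o matrix Q gives
#     F = Q' (U'x  *  V'e) + B         (elementwise product, a*k + b*k + k*o + o
#                                        parameters)
# Each position's F is shrunk to a sparse code by the closed-form
# soft-threshold solution of the l1-penalized proximal objective
# 0.5 * ||z - F||^2 + lambda * ||z||_1, positions are averaged, and the result
# is L2-normalized.

#' Parameters of the factorized bilinear encoding layer
#'
#' Initializes `U`, `V`, `Q` with variance-scaled uniform noise and `B` at
#' zero.
#'
#' @param a dimensionality of the first (local-path) feature.
#' @param b dimensionality of the second (global-path) feature.
#' @param k factorization rank, `k <= min(a, b)`.
#' @param o output dimensionality.
#' @param lambda non-negative sparsity weight of the soft-threshold step.
#' @param seed optional seed for reproducible initialization.
#' @return an object of class `fbe_params` with fields `U` (`a x k`),
#'   `V` (`b x k`), `Q` (`k x o`), `B` (length `o`), `lambda`.
#' @export
fbe_params <- function(a, b, k = 2L, o = NULL, lambda = 0.01, seed = NULL) {
  o <- as.integer(o %||% a)
  k <- as.integer(k)
  if (k < 1 || k > min(a, b)) stop("rank k must satisfy 1 <= k <= min(a, b)",
                                   call. = FALSE)
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  draw <- function() {
    lim_u <- sqrt(6 / (a + k)); lim_v <- sqrt(6 / (b + k)); lim_q <- sqrt(6 / (k + o))
    list(U = matrix(stats::runif(a * k, -lim_u, lim_u), a, k),
         V = matrix(stats::runif(b * k, -lim_v, lim_v), b, k),
         Q = matrix(stats::runif(k * o, -lim_q, lim_q), k, o))
  }
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(U = v$U, V = v$V, Q = v$Q, B = numeric(o),
                 lambda = lambda, k = k, o = o, a = as.integer(a),
                 b = as.integer(b)),
            class = "fbe_params")
}

#' Number of trainable parameters of an FBE layer
#'
#' `a*k + b*k + k*o + o`, versus `o*(a*b + 1)` for the unfactorized bilinear
#' form.
#'
#' @param params an [fbe_params] object.
#' @return integer count.
#' @export
fbe_param_count <- function(params) {
  with(params, a * k + b * k + k * o + o)
}

#' Low-rank bilinear interaction of two feature vectors
#'
#' Computes `F = Q'(U'x * V'e) + B`. Equivalent to the full bilinear form with
#' per-output interaction matrices `W_i = U diag(Q[, i]) V'`.
#'
#' @param x numeric vector of length `a`.
#' @param e numeric vector of length `b`.
#' @param params an [fbe_params] object.
#' @return numeric vector of length `o`.
#' @export
factorized_bilinear <- function(x, e, params) {
  if (length(x) != nrow(params$U) || length(e) != nrow(params$V)) {
    stop("feature lengths do not match the factorization matrices", call. = FALSE)
  }
  drop(crossprod(params$Q, drop(crossprod(params$U, x)) *
                             drop(crossprod(params$V, e)))) + params$B
}

#' Soft-thresholding (shrinkage) operator
#'
#' Componentwise closed-form minimizer of
#' `0.5 * (z - F)^2 + lambda * |z|`: `sign(F) * max(|F| - lambda, 0)`.
#'
#' @param F numeric vector or matrix.
#' @param lambda non-negative threshold.
#' @return object of the same shape as `F`; entries with `|F| < lambda` are
#'   exactly zero.
#' @export
soft_threshold <- function(F, lambda) {
  if (length(lambda) != 1 || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative value", call. = FALSE)
  assert_finite(F, "bilinear output")
  sign(F) * pmax(abs(F) - lambda, 0)
}

#' Paired position-aligned features for fusion
#'
#' @param Xt `L x a` matrix of local-path features, one row per position.
#' @param Et `L x b` matrix of global-path features after stretching.
#' @return an object of class `paired_features`.
#' @export
paired_features <- function(Xt, Et) {
  Xt <- as.matrix(Xt); Et <- as.matrix(Et)
  if (nrow(Xt) != nrow(Et)) stop("paired features must share the row count",
                                 call. = FALSE)
  if (nrow(Xt) < 1) stop("paired features must contain at least one position",
                         call. = FALSE)
  structure(list(Xt = Xt, Et = Et, L = nrow(Xt)), class = "paired_features")
}

#' Fuse paired features through the FBE layer
#'
#' Applies the low-rank bilinear interaction and soft-threshold sparse coding
#' at every position, averages the position codes, and L2-normalizes the mean.
#'
#' @param feats a [paired_features] object.
#' @param params an [fbe_params] object.
#' @return numeric vector of length `o` with unit Euclidean norm (all-zero
#'   codes stay zero).
#' @export
fbe_fuse <- function(feats, params) {
  stopifnot(inherits(feats, "paired_features"))
  fbe_block_forward(feats$Xt, feats$Et, params)$out
}

# Forward with cache for backprop. Xt: L x a, Et: L x b.
fbe_block_forward <- function(Xt, Et, params) {
  P <- Xt %*% params$U                          # L x k
  M <- Et %*% params$V                          # L x k
  H <- P * M
  F <- H %*% params$Q + rep(params$B, each = nrow(H))   # L x o
  Z <- soft_threshold(F, params$lambda)
  zbar <- colMeans(Z)
  r <- sqrt(sum(zbar^2))
  out <- if (r < 1e-12) zbar * 0 else zbar / r
  list(out = out,
       cache = list(Xt = Xt, Et = Et, P = P, M = M, H = H,
                    alive = abs(F) > params$lambda, zbar = zbar, r = r))
}

# Backward: subgradient 0 inside the soft-threshold dead zone; outside it the
# shrinkage has unit slope.
fbe_block_backward <- function(dout, params, cache) {
  L <- nrow(cache$Xt)
  if (cache$r < 1e-12) {
    dzbar <- numeric(length(dout))
  } else {
    y <- cache$zbar / cache$r
    dzbar <- (dout - y * sum(y * dout)) / cache$r
  }
  dZ <- matrix(dzbar / L, L, length(dzbar), byrow = TRUE)
  dF <- dZ * cache$alive
  dB <- colSums(dF)
  dQ <- crossprod(cache$H, dF)
  dH <- dF %*% t(params$Q)
  dP <- dH * cache$M
  dM <- dH * cache$P
  dU <- crossprod(cache$Xt, dP)
  dV <- crossprod(cache$Et, dM)
  dXt <- dP %*% t(params$U)
  dEt <- dM %*% t(params$V)
  list(dXt = dXt, dEt = dEt, dU = dU, dV = dV, dQ = dQ, dB = dB)
}
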