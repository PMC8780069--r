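# Global orderless path: dictionary-based residual encoding of convolutional
# descriptors with per-channel suppression of maximal encoding responses.
#
# Given m descriptors x_i (rows of X, m = h*w) and n codewords d_j with
# learnable scaling factors s_j, the residuals r_ij = x_i - d_j are softly
# assigned with weights
#     w_ij = softmax_j( -s_j * ||r_ij||^2 )
# and aggregated per codeword into e_j = sum_i w_ij r_ij, giving the n x c
# orderless encoding matrix E. Suppression then scales, within each channel
# (column of E), every entry attaining the column maximum by a factor
# alpha in [0, 1], leaving the rest untouched.

#' Construct a descriptor set from a flattened feature map
#'
#' @param X numeric matrix, one visual descriptor per row (`m x c`, `m = h*w`).
#' @param h,w spatial grid size the rows of `X` were flattened from.
#' @return an object of class `descriptor_set`.
#' @export
descriptor_set <- function(X, h, w) {
  X <- as.matrix(X)
  if (nrow(X) != h * w) stop("nrow(X) must equal h*w", call. = FALSE)
  if (nrow(X) < 1 || ncol(X) < 1) stop("descriptor set must be non-empty", call. = FALSE)
  assert_finite(X, "descriptor set")
  structure(list(X = X, h = h, w = w, m = nrow(X), c = ncol(X)),
            class = "descriptor_set")
}

#' Initialize a residual-encoding codebook
#'
#' Codewords are drawn uniformly in `[-1/sqrt(n), 1/sqrt(n)]` per component and
#' scaling factors uniformly in `(0, 1]`, the common initialization for
#' trainable encoding layers.
#'
#' @param n number of codewords.
#' @param c descriptor dimensionality (channels).
#' @param seed optional integer seed for reproducible initialization.
#' @return an object of class `codebook` with fields `D` (`n x c`) and `S`
#'   (length `n`).
#' @export
codebook_init <- function(n, c, seed = NULL) {
  stopifnot(n >= 1, c >= 1)
  draw <- function() {
    list(D = matrix(stats::runif(n * c, -1 / sqrt(n), 1 / sqrt(n)), n, c),
         S = stats::runif(n, .Machine$double.eps, 1))
  }
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(D = v$D, S = v$S, n = n, c = c), class = "codebook")
}

#' Soft-assignment weights of descriptors to codewords
#'
#' Row `i` holds the softmax over codewords `j` of `-s_j * ||x_i - d_j||^2`
#' (squared Euclidean norm of the full residual). Rows sum to one. The softmax
#' subtracts the per-row maximum before exponentiation for numerical stability.
#'
#' @param X a [descriptor_set] (or bare `m x c` matrix).
#' @param cb a [codebook].
#' @return `m x n` matrix of assignment weights.
#' @export
assign_weights <- function(X, cb) {
  Xm <- if (inherits(X, "descriptor_set")) X$X else as.matrix(X)
  if (ncol(Xm) != ncol(cb$D)) {
    stop("descriptor and codebook channel counts differ (",
         ncol(Xm), " vs ", ncol(cb$D), ")", call. = FALSE)
  }
  assert_finite(Xm, "descriptor set")
  assert_finite(cb$D, "codebook")
  r2 <- sq_dist(Xm, cb$D)                       # m x n squared residual norms
  logits <- -sweep(r2, 2, cb$S, `*`)
  softmax_rows(logits)
}

sq_dist <- function(X, D) {
  # ||x_i||^2 + ||d_j||^2 - 2 x_i . d_j, clipped at 0 against roundoff
  r2 <- outer(rowSums(X^2), rowSums(D^2), `+`) - 2 * X %*% t(D)
  pmax(r2, 0)
}

softmax_rows <- function(a) {
  a <- a - apply(a, 1, max)
  e <- exp(a)
  e / rowSums(e)
}

#' Aggregate soft-assigned residuals into the encoding matrix
#'
#' Computes `e_j = sum_i w_ij (x_i - d_j)`, one row per codeword.
#'
#' @param X a [descriptor_set] (or `m x c` matrix).
#' @param cb a [codebook].
#' @param W `m x n` assignment weights, e.g. from [assign_weights()].
#' @return `n x c` encoding matrix.
#' @export
residual_encode <- function(X, cb, W) {
  Xm <- if (inherits(X, "descriptor_set")) X$X else as.matrix(X)
  W <- as.matrix(W)
  if (nrow(W) != nrow(Xm) || ncol(W) != nrow(cb$D) || ncol(Xm) != ncol(cb$D)) {
    stop("inconsistent shapes among descriptors, codebook and weights",
         call. = FALSE)
  }
  crossprod(W, Xm) - colSums(W) * cb$D
}

#' Per-channel suppression of maximal encoding responses
#'
#' For each channel (column of `E`), every entry attaining the column maximum
#' is multiplied by `alpha`; all other entries pass through unchanged. Ties at
#' the maximum are all suppressed, which keeps the operation deterministic and
#' order-independent. `alpha = 1` is the identity.
#'
#' @param E `n x c` encoding matrix.
#' @param alpha suppressing factor in `[0, 1]`.
#' @return matrix of the same shape as `E`.
#' @export
global_suppress <- function(E, alpha) {
  E <- as.matrix(E)
  assert_finite(E, "encoding matrix")
  P <- global_suppress_mask(E, alpha)
  P * E
}

#' Non-maximal mask for global suppression
#'
#' @param E `n x c` encoding matrix.
#' @param alpha suppressing factor in `[0, 1]`.
#' @return matrix with entries `alpha` at per-column maxima and 1 elsewhere.
#' @export
global_suppress_mask <- function(E, alpha) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  E <- as.matrix(E)
  colmax <- apply(E, 2, max)
  ifelse(E == rep(colmax, each = nrow(E)), alpha, 1)
}

#' Suppressed residual encoding of a convolutional feature map
#'
#' Composes descriptor flattening, soft assignment, residual aggregation and
#' per-channel maximal-response suppression into the global orderless path.
#'
#' @param featmap `c x h x w` array (channel-first) or `h x w x c` array with
#'   `channel_first = FALSE`.
#' @param cb a [codebook] with matching channel count.
#' @param alpha suppressing factor in `[0, 1]`.
#' @param channel_first whether `featmap` is `c x h x w` (default) or
#'   `h x w x c`.
#' @return `n x c` suppressed encoding matrix.
#' @export
encode_forward <- function(featmap, cb, alpha, channel_first = TRUE) {
  stopifnot(length(dim(featmap)) == 3)
  if (channel_first) featmap <- aperm(featmap, c(2, 3, 1))
  d <- dim(featmap)
  if (d[3] != ncol(cb$D)) {
    stop("feature-map channels (", d[3], ") do not match codebook (",
         ncol(cb$D), ")", call. = FALSE)
  }
  X <- descriptor_set(flatten_positions(featmap), d[1], d[2])
  W <- assign_weights(X, cb)
  E <- residual_encode(X, cb, W)
  global_suppress(E, alpha)
}

# Differentiable building block used inside the network: forward with cache.
encode_block_forward <- function(Xm, D, S, alpha) {
  r2 <- sq_dist(Xm, D)
  logits <- -sweep(r2, 2, S, `*`)
  W <- softmax_rows(logits)
  E <- crossprod(W, Xm) - colSums(W) * D
  P <- global_suppress_mask(E, alpha)
  list(out = P * E, cache = list(Xm = Xm, D = D, S = S, r2 = r2, W = W, P = P))
}

# Backward through suppression, aggregation, softmax assignment and the
# squared-distance logits. The suppression mask is piecewise constant in E, so
# its gradient is the mask itself.
encode_block_backward <- function(dout, cache) {
  Xm <- cache$Xm; D <- cache$D; S <- cache$S
  W <- cache$W; r2 <- cache$r2
  dE <- cache$P * dout
  # E = t(W) X - colSums(W) * D
  dX <- W %*% dE
  dD <- -colSums(W) * dE
  dW <- Xm %*% t(dE) - rep(rowSums(dE * D), each = nrow(Xm))
  # softmax rows: dA = W * (dW - rowSums(W * dW))
  dA <- W * (dW - rowSums(W * dW))
  # A = -s_j * r2_ij
  dS <- -colSums(dA * r2)
  dR2 <- -sweep(dA, 2, S, `*`)
  # r2_ij = ||x_i - d_j||^2
  dX <- dX + 2 * (rowSums(dR2) * Xm - dR2 %*% D)
  dD <- dD + 2 * (colSums(dR2) * D - crossprod(dR2, Xm))
  list(dX = dX, dD = dD, dS = dS)
}
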