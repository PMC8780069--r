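# Local spatial path: stochastic suppression of per-channel activation peaks
# during training. For a channel map X_l (flattened to length m = h*w), the
# non-maximal mask holds beta at every position attaining max(X_l) and 1
# elsewhere. Each channel is selected with Bernoulli probability p; a selected
# channel receives ct (uniform on 1..ct_max) successive suppression passes.
# At inference the whole map passes through untouched.

#' Configuration for local spatial suppression
#'
#' @param beta suppressing factor in `[0, 1]` applied to peak positions.
#' @param p Bernoulli probability that a channel is selected for suppression.
#' @param ct_max upper bound of the per-channel pass count; the number of
#'   passes is drawn uniformly from `1..ct_max`.
#' @param recompute if `TRUE` (default) the peak mask is recomputed from the
#'   running map on every pass, so `ct` passes attenuate the `ct` largest
#'   peaks; if `FALSE` a single mask is applied `ct` times, rescaling the same
#'   peak by `beta^ct`.
#' @return an object of class `local_suppression_config`.
#' @export
local_suppression_config <- function(beta = 0.1, p = 0.5, ct_max = 3L,
                                     recompute = TRUE) {
  if (length(beta) != 1 || !is.finite(beta) || beta < 0 || beta > 1)
    stop("beta must be a single value in [0, 1]", call. = FALSE)
  if (length(p) != 1 || !is.finite(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]", call. = FALSE)
  ct_max <- as.integer(ct_max)
  if (is.na(ct_max) || ct_max < 1) stop("ct_max must be >= 1", call. = FALSE)
  structure(list(beta = beta, p = p, ct_max = ct_max,
                 recompute = isTRUE(recompute)),
            class = "local_suppression_config")
}

#' Non-maximal mask of a channel map
#'
#' @param x numeric vector (flattened channel map).
#' @param beta value placed at positions attaining `max(x)`; all other
#'   positions receive 1. All ties at the maximum are marked.
#' @return numeric vector of the same length with entries in `{beta, 1}`.
#' @export
make_local_mask <- function(x, beta) {
  if (length(x) < 1) stop("channel map must be non-empty", call. = FALSE)
  assert_finite(x, "channel map")
  ifelse(x == max(x), beta, 1)
}

#' Stochastic local spatial suppression
#'
#' Applies peak suppression channel-wise in training mode and is the exact
#' identity in evaluation mode. Draws come from the current R random stream;
#' seed it in the caller (the training loop does) for reproducibility.
#'
#' @param X `c x m` matrix, one flattened spatial channel map per row.
#' @param cfg a [local_suppression_config].
#' @param training logical; suppression is active only when `TRUE`.
#' @return a list with `out` (`c x m` matrix) and `factor` (`c x m` matrix of
#'   cumulative per-entry attenuation factors, 1 everywhere that was not
#'   suppressed); `out == X * factor`.
#' @export
local_suppress <- function(X, cfg, training = TRUE) {
  X <- as.matrix(X)
  stopifnot(inherits(cfg, "local_suppression_config"))
  assert_finite(X, "spatial map")
  fac <- matrix(1, nrow(X), ncol(X))
  if (training && cfg$p > 0 && cfg$beta < 1) {
    r <- stats::runif(nrow(X)) < cfg$p
    for (l in which(r)) {
      ct <- sample.int(cfg$ct_max, 1L)
      xl <- X[l, ]
      fl <- rep(1, length(xl))
      if (cfg$recompute) {
        for (i in seq_len(ct)) {
          mask <- make_local_mask(xl, cfg$beta)
          xl <- mask * xl
          fl <- fl * mask
        }
      } else {
        mask <- make_local_mask(xl, cfg$beta)
        fl <- mask^ct
        xl <- fl * X[l, ]
      }
      X[l, ] <- xl
      fac[l, ] <- fl
    }
  } else if (training && cfg$p > 0) {
    # beta == 1: masks are all-ones but the random draws are still consumed so
    # that a run is reproducible regardless of beta.
    r <- stats::runif(nrow(X)) < cfg$p
    for (l in which(r)) sample.int(cfg$ct_max, 1L)
  }
  list(out = X, factor = fac)
}
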