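#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Arrays are stored column-major as
# (H, W, C, N): height, width, channel, batch.

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a locally seeded RNG
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so library internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Bilinear image resize
#'
#' Resizes a 2-D intensity matrix with bilinear interpolation. Used to bring
#' heterogeneous slice resolutions to the network input size and to upsample
#' activation heatmaps for display.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return numeric matrix of size `out_h` by `out_w`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # sample at pixel centers (align corners = FALSE convention)
  ys <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x1, drop = FALSE]
  c_ <- img[y1, x0, drop = FALSE]; d <- img[y1, x1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
  bot <- c_ * outer(rep(1, out_h), 1 - wx) + d * outer(rep(1, out_h), wx)
  top * (1 - wy) + bot * wy
}

# Flatten a (7,7,c) feature map to the m x c descriptor matrix (row = spatial
# position, column-major over (H, W)).
flatten_positions <- function(fm) {
  d <- dim(fm)
  matrix(fm, d[1] * d[2], d[3])
}

l2_normalize <- function(z, eps = 1e-12) {
  r <- sqrt(sum(z^2))
  if (r < eps) return(z * 0)
  z / r
}
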