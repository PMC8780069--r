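# Minimal neural-network core: convolution (im2col over OpenBLAS GEMM), batch
# normalization, ReLU, max pooling and dense layers, each with a hand-derived
# backward pass. Layout is (H, W, C, N) column-major.

pad4d <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# im2col: returns (oh*ow*N) x (C*kh*kw) matrix; column blocks ordered with the
# channel index fastest, then kernel row, then kernel column, matching
# matrix(aperm(w, c(3, 1, 2, 4)), C*kh*kw, Cout).
im2col <- function(xp, kh, kw, stride, oh, ow) {
  d <- dim(xp); C <- d[3]; N <- d[4]
  col <- matrix(0, oh * ow * N, C * kh * kw)
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      s <- xp[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE]
      s <- aperm(s, c(1, 2, 4, 3))              # (oh, ow, N, C)
      blk <- (kj - 1L) * kh + (ki - 1L)
      col[, blk * C + seq_len(C)] <- matrix(s, oh * ow * N, C)
    }
  }
  col
}

col2im <- function(dcol, dims_p, kh, kw, stride, oh, ow) {
  C <- dims_p[3]; N <- dims_p[4]
  dxp <- array(0, dims_p)
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  for (kj in seq_len(kw)) {
    for (ki in seq_len(kh)) {
      blk <- (kj - 1L) * kh + (ki - 1L)
      s <- array(dcol[, blk * C + seq_len(C)], c(oh, ow, N, C))
      s <- aperm(s, c(1, 2, 4, 3))              # (oh, ow, C, N)
      dxp[ri + (ki - 1L), ci + (kj - 1L), , ] <-
        dxp[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE] + s
    }
  }
  dxp
}

conv2d_forward <- function(x, w, b = NULL, stride = 1L, pad = 0L,
                           keep_cache = FALSE) {
  d <- dim(x); kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  stopifnot(dim(w)[3] == d[3])
  xp <- pad4d(x, pad)
  dp <- dim(xp)
  oh <- (dp[1] - kh) %/% stride + 1L
  ow <- (dp[2] - kw) %/% stride + 1L
  col <- im2col(xp, kh, kw, stride, oh, ow)
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), dim(w)[3] * kh * kw, Cout)
  out <- col %*% wm
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  out4 <- aperm(array(out, c(oh, ow, d[4], Cout)), c(1, 2, 4, 3))
  cache <- NULL
  if (keep_cache) {
    cache <- list(col = col, dims_p = dp, kh = kh, kw = kw, stride = stride,
                  oh = oh, ow = ow, pad = pad, wdim = dim(w), has_b = !is.null(b))
  }
  list(out = out4, cache = cache)
}

conv2d_backward <- function(dout, w, cache) {
  kh <- cache$kh; kw <- cache$kw; Cin <- cache$wdim[3]; Cout <- cache$wdim[4]
  d <- dim(dout)                                # (oh, ow, Cout, N)
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), d[1] * d[2] * d[4], Cout)
  wm <- matrix(aperm(w, c(3, 1, 2, 4)), Cin * kh * kw, Cout)
  dwm <- crossprod(cache$col, dm)
  dw <- aperm(array(dwm, c(Cin, kh, kw, Cout)), c(2, 3, 1, 4))
  db <- if (cache$has_b) colSums(dm) else NULL
  dcol <- dm %*% t(wm)
  dxp <- col2im(dcol, cache$dims_p, kh, kw, cache$stride, cache$oh, cache$ow)
  pad <- cache$pad
  dx <- if (pad > 0) {
    dp <- cache$dims_p
    dxp[pad + seq_len(dp[1] - 2 * pad), pad + seq_len(dp[2] - 2 * pad), , ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dw = dw, db = db)
}

bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    n <- nrow(xm)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    unb <- if (n > 1) v * n / (n - 1) else v
    running_var <- (1 - momentum) * running_var + momentum * unb
  } else {
    mu <- running_mean
    v <- running_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = nrow(xm))) * rep(invstd, each = nrow(xm))
  ym <- xhat * rep(gamma, each = nrow(xm)) + rep(beta, each = nrow(xm))
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(out = y,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$dims; C <- d[3]
  dym <- matrix(aperm(dout, c(1, 2, 4, 3)), d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  if (cache$training) {
    t1 <- dym - rep(dbeta / n, each = n) - xhat * rep(dgamma / n, each = n)
    dxm <- t1 * rep(gamma * cache$invstd, each = n)
  } else {
    dxm <- dym * rep(gamma * cache$invstd, each = n)
  }
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, mask) dout * mask

maxpool_forward <- function(x, k, stride, pad = 0L) {
  xp <- pad4d(x, pad)
  if (pad > 0) xp[xp == 0 & pad4d(array(1, dim(x)), pad) == 0] <- -Inf
  dp <- dim(xp)
  oh <- (dp[1] - k) %/% stride + 1L
  ow <- (dp[2] - k) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  best <- array(-Inf, c(oh, ow, dp[3], dp[4]))
  arg <- array(0L, c(oh, ow, dp[3], dp[4]))
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      s <- xp[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE]
      upd <- s > best
      best[upd] <- s[upd]
      arg[upd] <- (kj - 1L) * k + ki
    }
  }
  list(out = best,
       cache = list(arg = arg, dims_p = dp, k = k, stride = stride, pad = pad,
                    dims = dim(x), oh = oh, ow = ow))
}

maxpool_backward <- function(dout, cache) {
  k <- cache$k
  dxp <- array(0, cache$dims_p)
  ri <- seq.int(1L, by = cache$stride, length.out = cache$oh)
  ci <- seq.int(1L, by = cache$stride, length.out = cache$ow)
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      m <- cache$arg == (kj - 1L) * k + ki
      if (!any(m)) next
      g <- dout * m
      dxp[ri + (ki - 1L), ci + (kj - 1L), , ] <-
        dxp[ri + (ki - 1L), ci + (kj - 1L), , , drop = FALSE] + g
    }
  }
  pad <- cache$pad
  if (pad > 0) {
    d <- cache$dims
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  } else dxp
}
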