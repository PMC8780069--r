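# Factorized bilinear fusion with soft-threshold sparse coding.

test_that("the low-rank interaction matches hand and full-matrix oracles", {
  # bilinear annihilation: zero input collapses to the bias
  p <- fbe_params(3, 3, k = 2, o = 4, lambda = 0, seed = 1)
  p$B <- c(1, -2, 0.5, 0)
  expect_equal(factorized_bilinear(numeric(3), rnorm(3), p), p$B)
  expect_equal(factorized_bilinear(rnorm(3), numeric(3), p), p$B)

  # hand case: (U'x)(V'e) = 2 * 2
  ph <- structure(list(U = matrix(1, 2, 1), V = matrix(1, 2, 1),
                       Q = matrix(1, 1, 1), B = 0, lambda = 0),
                  class = "fbe_params")
  expect_equal(factorized_bilinear(c(1, 1), c(1, 1), ph), 4)

  expect_error(factorized_bilinear(rnorm(5), rnorm(3), p), "lengths")

  # explicit full-matrix oracle on random small instances
  set.seed(303)
  for (i in 1:100) {
    a <- sample(2:5, 1); b <- sample(2:5, 1)
    k <- sample(1:min(a, b), 1); o <- sample(1:4, 1)
    pp <- fbe_params(a, b, k = k, o = o, lambda = 0)
    x <- rnorm(a); e <- rnorm(b)
    expect_lt(max_rel_err(factorized_bilinear(x, e, pp),
                          full_bilinear_oracle(x, e, pp$U, pp$V, pp$Q, pp$B)),
              1e-9)
  }
})

test_that("soft thresholding is the shrinkage minimizer", {
  expect_equal(soft_threshold(c(0.4, -1.2), 0), c(0.4, -1.2))
  expect_equal(soft_threshold(c(0.5, -0.5, 0.1), 0.2), c(0.3, -0.3, 0))
  expect_error(soft_threshold(c(1, 2), -0.1), "non-negative")

  # closed form attains the grid minimum of the proximal objective
  set.seed(404)
  grid <- seq(-3, 3, by = 1e-3)
  for (i in 1:200) {
    f <- rnorm(1, sd = 1.2); lam <- runif(1, 0, 1)
    z <- soft_threshold(f, lam)
    expect_lte(shrinkage_objective(z, f, lam),
               min(shrinkage_objective(grid, f, lam)) + 1e-12)
  }
})

test_that("sparsity grows monotonically with the penalty", {
  set.seed(505)
  F <- rnorm(50, sd = 2)
  nnz <- sapply(c(0, 0.5, 1, 2, 4, 100), function(l) sum(soft_threshold(F, l) != 0))
  expect_true(all(diff(nnz) <= 0))
  expect_equal(nnz[length(nnz)], 0)
  # exact zeros inside the dead zone
  expect_true(all(soft_threshold(F, 2)[abs(F) < 2] == 0))
})

test_that("the factorization is more economical than full bilinear pooling", {
  for (dims in list(c(8, 8, 2, 8), c(2048, 2048, 2, 2048), c(32, 16, 4, 10))) {
    p <- fbe_params(dims[1], dims[2], k = dims[3], o = dims[4], lambda = 0.01)
    expect_lt(fbe_param_count(p), dims[4] * (dims[1] * dims[2] + 1))
  }
  expect_error(fbe_params(4, 4, k = 5), "rank")
})

test_that("fusion averages position codes and normalizes the result", {
  set.seed(606)
  p <- fbe_params(6, 6, k = 2, o = 5, lambda = 0.01)
  # identical positions: the mean equals the single-position code
  x <- rnorm(6); e <- rnorm(6)
  one <- fbe_fuse(paired_features(t(x), t(e)), p)
  rep3 <- fbe_fuse(paired_features(matrix(x, 3, 6, byrow = TRUE),
                                   matrix(e, 3, 6, byrow = TRUE)), p)
  expect_equal(one, rep3, tolerance = 1e-12)
  expect_equal(sum(one^2), 1, tolerance = 1e-10)

  # L = 2 hand case engineered to give position codes (1,0) and (0,1):
  # identity factorization, no penalty; mean (0.5, 0.5) normalizes to
  # (0.7071, 0.7071)
  pid <- structure(list(U = diag(2), V = diag(2), Q = diag(2),
                        B = c(0, 0), lambda = 0), class = "fbe_params")
  out2 <- fbe_fuse(paired_features(diag(2), diag(2)), pid)
  expect_equal(out2, rep(1 / sqrt(2), 2), tolerance = 1e-12)

  expect_error(paired_features(matrix(0, 2, 3), matrix(0, 3, 3)), "row count")

  # default-scale contract: 2048-channel paths fuse to a 2048 vector
  pbig <- fbe_params(2048, 2048, k = 2, o = 2048, lambda = 0.01, seed = 2)
  out <- fbe_fuse(paired_features(matrix(rnorm(49 * 2048), 49, 2048),
                                  matrix(rnorm(49 * 2048), 49, 2048)), pbig)
  expect_length(out, 2048)
  expect_equal(sum(out^2), 1, tolerance = 1e-10)
})

test_that("fusion gradients match finite differences away from the kinks", {
  set.seed(707)
  L <- 4; a <- 3; b <- 3; k <- 2; o <- 2
  p <- fbe_params(a, b, k = k, o = o, lambda = 0.05, seed = 7)
  Xt <- matrix(rnorm(L * a), L, a); Et <- matrix(rnorm(L * b), L, b)
  fw <- dsenet:::fbe_block_forward(Xt, Et, p)
  Fmat <- fw$cache$H %*% p$Q + rep(p$B, each = L)
  # keep clear of the |F| = lambda kinks so finite differences are valid
  expect_gt(min(abs(abs(Fmat) - p$lambda)), 1e-3)
  dz <- rnorm(o)
  bk <- dsenet:::fbe_block_backward(dz, p, fw$cache)
  lf <- function(Xt., Et., U, V, Q, B) {
    pp <- p; pp$U <- U; pp$V <- V; pp$Q <- Q; pp$B <- B
    sum(dsenet:::fbe_block_forward(Xt., Et., pp)$out * dz)
  }
  checks <- list(
    list(bk$dXt, function(v) lf(matrix(v, L, a), Et, p$U, p$V, p$Q, p$B), Xt),
    list(bk$dEt, function(v) lf(Xt, matrix(v, L, b), p$U, p$V, p$Q, p$B), Et),
    list(bk$dU, function(v) lf(Xt, Et, matrix(v, a, k), p$V, p$Q, p$B), p$U),
    list(bk$dV, function(v) lf(Xt, Et, p$U, matrix(v, b, k), p$Q, p$B), p$V),
    list(bk$dQ, function(v) lf(Xt, Et, p$U, p$V, matrix(v, k, o), p$B), p$Q),
    list(bk$dB, function(v) lf(Xt, Et, p$U, p$V, p$Q, v), p$B))
  for (ch in checks) {
    g <- num_grad(ch[[2]], as.numeric(ch[[3]]))
    expect_lt(max_rel_err(as.numeric(ch[[1]]), g), 1e-4)
  }
})
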