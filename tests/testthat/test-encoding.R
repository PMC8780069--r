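# Residual encoding of visual descriptors and per-channel suppression of
# maximal encoding responses.

make_cb <- function(D, S) {
  structure(list(D = D, S = S, n = nrow(D), c = ncol(D)), class = "codebook")
}

test_that("assignment weights follow the softmax of scaled squared residuals", {
  # single codeword: softmax over one element
  cb1 <- make_cb(matrix(c(1, 2), 1, 2), 0.7)
  W <- assign_weights(matrix(rnorm(10), 5, 2), cb1)
  expect_equal(unname(W), matrix(1, 5, 1))

  # zero scaling factors: uniform weights regardless of residuals
  cb0 <- make_cb(matrix(rnorm(6), 3, 2), rep(0, 3))
  W0 <- assign_weights(matrix(rnorm(8), 4, 2), cb0)
  expect_equal(unname(W0), matrix(1 / 3, 4, 3))

  # hand-evaluated two-codeword case: exp(0) / (exp(0) + exp(-1))
  cb <- make_cb(matrix(c(0, 1), 2, 1), c(1, 1))
  W2 <- assign_weights(descriptor_set(matrix(0, 1, 1), 1, 1), cb)
  expect_equal(drop(W2), c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)

  expect_error(assign_weights(matrix(0, 1, 3), cb), "channel")
  expect_error(assign_weights(matrix(NaN, 1, 1), cb), "non-finite")
})

test_that("assignment rows are stochastic for random problem sizes", {
  set.seed(101)
  for (i in 1:1000) {
    m <- sample(1:16, 1); n <- sample(1:4, 1); c <- sample(1:5, 1)
    cb <- make_cb(matrix(rnorm(n * c), n, c), runif(n, 0, 2))
    W <- assign_weights(matrix(rnorm(m * c, sd = 2), m, c), cb)
    expect_true(all(abs(rowSums(W) - 1) < 1e-6))
    expect_true(all(W > 0))
  }
})

test_that("vectorized encoding matches the naive triple-loop oracle", {
  set.seed(202)
  for (i in 1:100) {
    m <- sample(1:16, 1); n <- sample(1:4, 1); c <- sample(1:5, 1)
    X <- matrix(rnorm(m * c), m, c)
    D <- matrix(rnorm(n * c), n, c)
    S <- runif(n, 0, 2)
    cb <- make_cb(D, S)
    W <- assign_weights(X, cb)
    E <- residual_encode(X, cb, W)
    ref <- naive_encoding(X, D, S)
    expect_lt(max(abs(W - ref$W)), 1e-9)
    expect_lt(max(abs(E - ref$E)), 1e-9)
  }
})

test_that("residual aggregation annihilates exact codeword matches", {
  # all descriptors equal to codeword 1: residual row 1 is exactly zero
  D <- matrix(c(1, 2, -1, 0), 2, 2, byrow = TRUE)
  X <- matrix(rep(c(1, 2), each = 4), 4, 2)
  cb <- make_cb(D, c(0.5, 0.5))
  E <- residual_encode(X, cb, assign_weights(X, cb))
  expect_equal(E[1, ], c(0, 0))

  # single codeword with unit weights: e_1 is the plain residual sum
  cb1 <- make_cb(matrix(c(0.5, -0.5), 1, 2), 1)
  X1 <- matrix(rnorm(6), 3, 2)
  E1 <- residual_encode(X1, cb1, matrix(1, 3, 1))
  expect_equal(drop(E1), colSums(sweep(X1, 2, c(0.5, -0.5))), tolerance = 1e-12)
})

test_that("per-channel suppression scales exactly the column maxima", {
  E <- matrix(c(3, 1, 2), 3, 1)
  expect_equal(unname(global_suppress(E, 0)), matrix(c(0, 1, 2), 3, 1))
  # ties at the maximum are all suppressed
  expect_equal(unname(global_suppress(matrix(c(2, 2), 2, 1), 0.5)),
               matrix(c(1, 1), 2, 1))
  # alpha = 1 is the exact identity
  set.seed(7)
  R <- matrix(rnorm(40), 8, 5)
  expect_identical(global_suppress(R, 1), R)
  expect_error(global_suppress(R, 1.2), "alpha")

  # locality: for untied columns exactly one entry changes per channel and
  # unchanged entries are bitwise identical
  for (i in 1:20) {
    R <- matrix(rnorm(6 * 4), 6, 4)
    Rs <- global_suppress(R, 0.3)
    changed <- Rs != R
    expect_equal(unname(colSums(changed)), rep(1, 4))
    expect_identical(Rs[!changed], R[!changed])
  }

  # monotone attenuation of the suppressed maximum in alpha
  col <- matrix(c(5, 1, -2), 3, 1)
  vals <- sapply(seq(0, 1, by = 0.1), function(a) max(global_suppress(col, a)))
  expect_true(all(diff(vals) >= 0))
})

test_that("encode_forward composes the path and honors the shape contract", {
  set.seed(5)
  cb <- codebook_init(8, 2048, seed = 9)
  fm <- array(rnorm(2048 * 7 * 7), c(2048, 7, 7))
  E <- encode_forward(fm, cb, alpha = 0.5)
  expect_equal(dim(E), c(8L, 2048L))
  # alpha = 1 equals the unsuppressed encoding
  X <- descriptor_set(flatten_positions(aperm(fm, c(2, 3, 1))), 7, 7)
  E1 <- residual_encode(X, cb, assign_weights(X, cb))
  expect_equal(encode_forward(fm, cb, 1), E1, tolerance = 1e-12)
  expect_error(encode_forward(fm, codebook_init(4, 16), 0.5), "channels")
})

test_that("encoding block gradients match central finite differences", {
  set.seed(77)
  m <- 4; c <- 3; n <- 2; alpha <- 0.3
  Xm <- matrix(rnorm(m * c), m, c)
  D <- matrix(rnorm(n * c), n, c)
  S <- runif(n, 0.2, 1)
  dout <- matrix(rnorm(n * c), n, c)
  loss <- function(Xm., D., S.)
    sum(dsenet:::encode_block_forward(Xm., D., S., alpha)$out * dout)
  fw <- dsenet:::encode_block_forward(Xm, D, S, alpha)
  bk <- dsenet:::encode_block_backward(dout, fw$cache)
  gX <- num_grad(function(v) loss(matrix(v, m, c), D, S), as.numeric(Xm))
  gD <- num_grad(function(v) loss(Xm, matrix(v, n, c), S), as.numeric(D))
  gS <- num_grad(function(v) loss(Xm, D, v), S)
  expect_lt(max_rel_err(bk$dX, matrix(gX, m, c)), 1e-4)
  expect_lt(max_rel_err(bk$dD, matrix(gD, n, c)), 1e-4)
  expect_lt(max_rel_err(bk$dS, gS), 1e-4)
})
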