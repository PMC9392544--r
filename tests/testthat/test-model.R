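# brute-force oracles for the convolution and pooling primitives
conv_oracle <- function(x, w, b, act = identity) {
  L <- nrow(x); s <- dim(w)[1]; r <- dim(w)[3]
  out <- matrix(0, L - s + 1, r)
  for (l in seq_len(L - s + 1)) {
    for (j in seq_len(r)) {
      acc <- b[j]
      for (i in seq_len(s)) {
        for (c in seq_len(ncol(x))) acc <- acc + x[l + i - 1, c] * w[i, c, j]
      }
      out[l, j] <- act(acc)
    }
  }
  out
}

pool_oracle <- function(x, d) {
  k <- nrow(x) %/% d
  out <- matrix(0, k, ncol(x))
  for (j in seq_len(k)) {
    for (c in seq_len(ncol(x))) out[j, c] <- max(x[((j - 1) * d + 1):(j * d), c])
  }
  out
}

test_that("the default architecture reproduces the published shapes and counts", {
  arch <- default_architecture()
  sh <- arch$shapes
  expect_equal(sh$params,
               c(9856, 0, 32832, 0, 8224, 0, 2064, 264, 0,
                 11800, 7600, 5100, 52))
  expect_equal(sh$length,
               c(497, 124, 121, 30, 27, 6, 3, 2, 1, 1, 1, 1, 1))
  expect_equal(sh$features,
               c(128, 128, 64, 64, 32, 32, 16, 8, 8, 50, 25, 25, 2))
  expect_equal(sum(sh$params), 77792)
})

test_that("per-layer parameter formulas match the printed table rows", {
  expect_equal(param_count(layer_conv1d(128, 4), 19), 9856)
  expect_equal(param_count(layer_conv1d(64, 4), 128), 32832)
  expect_equal(param_count(layer_conv1d(32, 4), 64), 8224)
  expect_equal(param_count(layer_conv1d(16, 4), 32), 2064)
  expect_equal(param_count(layer_conv1d(8, 2), 16), 264)
  expect_equal(param_count(layer_lstm(50), 8), 11800)
  expect_equal(param_count(layer_lstm(25), 50), 7600)
  expect_equal(param_count(layer_lstm(25), 25), 5100)
  expect_equal(param_count(layer_dense(2), 25), 52)
  expect_equal(param_count(layer_maxpool1d(4), 128), 0)
})

test_that("conv1d_valid matches the nested-loop oracle on random instances", {
  set.seed(12)
  for (i in 1:100) {
    L <- sample(5:12, 1); C <- sample(1:3, 1)
    s <- sample(1:min(4, L), 1); r <- sample(1:3, 1)
    x <- matrix(rnorm(L * C), L, C)
    w <- array(rnorm(s * C * r), c(s, C, r))
    b <- rnorm(r)
    expect_equal(conv1d_valid(x, w, b), conv_oracle(x, w, b),
                 tolerance = 1e-6)
  }
  # identity kernel: s = 1, weight 1, bias 0, single channel/filter
  x <- matrix(rnorm(20), 20, 1)
  expect_equal(conv1d_valid(x, array(1, c(1, 1, 1)), 0), x)
  expect_error(conv1d_valid(matrix(0, 2, 1), array(1, c(3, 1, 1)), 0),
               "shorter")
})

test_that("maxpool1d matches its oracle and the printed lengths", {
  expect_equal(maxpool1d(matrix(c(1, 3, 2, 5)), 2), matrix(c(3, 5)))
  expect_equal(nrow(maxpool1d(matrix(0, 497, 2), 4)), 124)
  expect_equal(nrow(maxpool1d(matrix(0, 121, 2), 4)), 30)
  set.seed(13)
  for (i in 1:100) {
    L <- sample(4:15, 1); r <- sample(1:3, 1); d <- sample(1:min(4, L), 1)
    x <- matrix(rnorm(L * r), L, r)
    expect_equal(maxpool1d(x, d), pool_oracle(x, d), tolerance = 1e-6)
  }
  expect_error(maxpool1d(matrix(0, 2, 1), 3), "shorter")
})

test_that("channel permutation symmetry holds for the first conv layer", {
  set.seed(14)
  x <- matrix(rnorm(30 * 5), 30, 5)
  w <- array(rnorm(3 * 5 * 4), c(3, 5, 4))
  b <- rnorm(4)
  perm <- sample(5)
  expect_equal(conv1d_valid(x[, perm], w[, perm, , drop = FALSE], b),
               conv1d_valid(x, w, b))
})

test_that("shape propagation refuses impossible layouts", {
  expect_error(architecture_spec(c(3, 2), list(layer_conv1d(2, 5))),
               "kernel")
  expect_error(architecture_spec(c(10, 2), list(layer_lstm(3, TRUE),
                                                layer_dense(2))),
               "length-1")
})

test_that("the compiled network gradient matches finite differences", {
  arch <- tiny_arch(len = 20, ch = 3)
  a <- eegresp:::arch_to_cpp(arch)
  set.seed(42)
  X <- array(rnorm(20 * 3 * 6), c(20, 3, 6))
  Y <- matrix(0, 6, 2)
  Y[cbind(1:6, 1 + (1:6) %% 2)] <- 1
  p0 <- eegresp:::cpp_init_params(a, 7)
  lg <- eegresp:::cpp_loss_grad(a, p0, X, Y)
  eps <- 1e-6
  idx <- sort(sample(length(p0), 80))
  num <- vapply(idx, function(j) {
    pp <- p0; pp[j] <- pp[j] + eps
    pm <- p0; pm[j] <- pm[j] - eps
    (eegresp:::cpp_loss_grad(a, pp, X, Y)$loss -
       eegresp:::cpp_loss_grad(a, pm, X, Y)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - lg$grad[idx])), 1e-5)
})

test_that("the compiled forward pass agrees with an all-R reference network", {
  sigmoid <- function(z) 1 / (1 + exp(-z))
  lstm_ref <- function(x, wx, wh, b, return_seq) {
    u <- ncol(wh)
    h <- numeric(u); cs <- numeric(u)
    out <- matrix(0, nrow(x), u)
    for (t in seq_len(nrow(x))) {
      z <- wx %*% x[t, ] + wh %*% h + b
      gi <- sigmoid(z[1:u]); gf <- sigmoid(z[(u + 1):(2 * u)])
      gg <- tanh(z[(2 * u + 1):(3 * u)]); go <- sigmoid(z[(3 * u + 1):(4 * u)])
      cs <- gf * cs + gi * gg
      h <- go * tanh(cs)
      out[t, ] <- h
    }
    if (return_seq) out else out[nrow(x), , drop = FALSE]
  }

  arch <- architecture_spec(c(12, 2), list(
    layer_conv1d(3, 4), layer_maxpool1d(2),
    layer_lstm(5, TRUE), layer_lstm(2, FALSE), layer_dense(2)))
  a <- eegresp:::arch_to_cpp(arch)
  p <- eegresp:::cpp_init_params(a, 3)
  set.seed(15)
  p <- p + rnorm(length(p), sd = 0.05)  # perturb zero biases too
  x <- matrix(rnorm(24), 12, 2)

  take <- local({ at <- 0; function(n) { v <- p[(at + 1):(at + n)]; at <<- at + n; v } })
  w1 <- array(take(4 * 2 * 3), c(4, 2, 3)); b1 <- take(3)
  h <- maxpool1d(conv1d_valid(x, w1, b1, "relu"), 2)
  wx1 <- matrix(take(20 * 3), 20, 3); wh1 <- matrix(take(20 * 5), 20, 5)
  bl1 <- take(20)
  h <- lstm_ref(h, wx1, wh1, bl1, TRUE)
  wx2 <- matrix(take(8 * 5), 8, 5); wh2 <- matrix(take(8 * 2), 8, 2)
  bl2 <- take(8)
  h <- lstm_ref(h, wx2, wh2, bl2, FALSE)
  wd <- matrix(take(2 * 2), 2, 2); bd <- take(2)
  ref <- sigmoid(wd %*% h[1, ] + bd)

  out <- eegresp:::cpp_forward(a, p, array(x, c(12, 2, 1)))
  expect_equal(as.numeric(out), as.numeric(ref), tolerance = 1e-10)
})

test_that("training is deterministic and predicts normalised probabilities", {
  tens <- random_tensor(n = 40, len = 32, ch = 4, seed = 21)
  arch <- tiny_arch()
  cfg <- train_config(batch_size = 16, epochs = 2, seed = 5)
  m1 <- suppressWarnings(build_and_train(arch, tens, val = NULL, cfg))
  m2 <- suppressWarnings(build_and_train(arch, tens, val = NULL, cfg))
  expect_identical(m1$params, m2$params)

  p <- predict_proba(m1, tens)
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  expect_identical(colnames(p), levels(tens$labels))
  expect_equal(nrow(m1$history), 2)

  # architecture config round-trips through its plain-text form
  path <- tempfile(fileext = ".yml")
  write_architecture(default_architecture(), path)
  back <- read_architecture(path)
  expect_equal(back$shapes, default_architecture()$shapes)
})
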