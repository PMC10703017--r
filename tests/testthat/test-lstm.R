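# LSTM cell, bidirectional composition, densely linked stacking,
# cross-entropy and multi-scale fusion — each against a literal
# transcription of its defining equations.

zero_params <- function(input_dim, units) {
  lstm_params(input_dim, units, init = "zero")
}

test_that("all-zero parameters give the analytic gate values", {
  p <- zero_params(2L, 3L)
  p$b_f[] <- 0                      # fully zero, including forget bias
  st <- lstm_cell_step(c(5, -2), lstm_state(3L), p)
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
  # with c_{t-1} = 1: c_t = f*1 + i*0 = 0.5, h_t = 0.5 * tanh(0.5)
  st2 <- lstm_cell_step(c(5, -2), list(h = rep(0, 3), c = rep(1, 3)), p)
  expect_equal(st2$c, rep(0.5, 3))
  expect_equal(st2$h, rep(0.5 * tanh(0.5), 3))
  expect_equal(st2$h[1], 0.23106, tolerance = 1e-5)
})

test_that("the cell matches a literal equation transcription on random instances", {
  set.seed(71)
  for (rep in 1:25) {
    p <- lstm_params(2L, 3L, seed = rep)
    x <- rnorm(2)
    h0 <- runif(3, -0.5, 0.5)
    c0 <- rnorm(3)
    got <- lstm_cell_step(x, list(h = h0, c = c0), p)
    want <- oracle_lstm_step(x, h0, c0, p)
    expect_lt(max(abs(got$h - want$h), abs(got$c - want$c)), 1e-12)
  }
})

test_that("cell inputs are validated", {
  p <- zero_params(2L, 3L)
  expect_error(lstm_cell_step(c(1, 2, 3), lstm_state(3L), p), "length")
  expect_error(lstm_cell_step(c(NaN, 1), lstm_state(3L), p), "non-finite")
})

test_that("sequence unrolling matches the step oracle; T = 1 is a single step", {
  set.seed(72)
  p <- lstm_params(4L, 3L, seed = 5L)
  X <- matrix(rnorm(5 * 4), 5)
  H <- lstm_forward(X, p)
  expect_equal(H, oracle_lstm_forward(X, p), tolerance = 1e-12)
  expect_equal(lstm_forward(X, p, return_sequence = FALSE), H[5, ])
  x1 <- matrix(rnorm(4), 1)
  expect_equal(drop(lstm_forward(x1, p)),
               lstm_cell_step(x1[1, ], lstm_state(3L), p)$h)
  expect_error(lstm_forward(matrix(0, 0, 4), p), "empty")
})

test_that("saturated gates carry the cell state unchanged", {
  p <- zero_params(3L, 2L)
  p$b_f[] <- 20          # forget ~ 1
  p$b_i[] <- -20         # input ~ 0
  X <- matrix(rnorm(12), 4)
  st <- list(h = rep(0, 2), c = c(0.7, -1.2))
  for (t in 1:4) st <- lstm_cell_step(X[t, ], st, p)
  expect_equal(st$c, c(0.7, -1.2), tolerance = 1e-8)
})

test_that("gates stay in (0,1) and hidden states stay inside (-1,1)", {
  set.seed(73)
  for (rep in 1:20) {
    p <- lstm_params(3L, 4L, seed = 100L + rep)
    X <- matrix(rnorm(8 * 3, sd = 5), 8)
    H <- lstm_forward(X, p)
    expect_true(all(abs(H) < 1))
  }
})

test_that("bidirectional output concatenates the two directions per step", {
  set.seed(74)
  p <- bilstm_params(3L, 4L, seed = 9L)
  X <- matrix(rnorm(6 * 3), 6)
  H <- bilstm_forward(X, p)
  expect_equal(dim(H), c(6L, 8L))
  expect_equal(H, oracle_bilstm_forward(X, p), tolerance = 1e-12)
  # backward half equals running the forward pass on the reversed sequence
  Hb <- lstm_forward(X[6:1, ], p$backward)[6:1, ]
  expect_equal(H[, 5:8], Hb, tolerance = 1e-12)
  # non-sequence output is [h_f(T), h_b(1)]
  v <- bilstm_forward(X, p, return_sequence = FALSE)
  expect_equal(v, c(H[6, 1:4], H[1, 5:8]))
})

test_that("identical direction parameters on a palindrome give mirrored hidden states", {
  p <- bilstm_params(2L, 3L, seed = 4L)
  p$backward <- p$forward
  half <- matrix(rnorm(8), 4)
  X <- rbind(half, half[4:1, ])              # palindromic sequence
  H <- bilstm_forward(X, p)
  T_len <- nrow(X)
  for (t in seq_len(T_len)) {
    expect_equal(H[t, 1:3], H[T_len + 1 - t, 4:6], tolerance = 1e-12)
  }
})

test_that("dense linking with one layer reduces to the plain recurrent output", {
  set.seed(75)
  X <- matrix(rnorm(5 * 2), 5)
  for (bi in c(FALSE, TRUE)) {
    spec <- dense_link_spec(1L, 4L, bidirectional = bi, input_dim = 2L)
    ps <- dense_link_params(spec, seed = 3L)
    out <- dense_link_forward(X, spec, ps)
    plain <- if (bi) bilstm_forward(X, ps[[1]]) else lstm_forward(X, ps[[1]])
    expect_identical(out, cbind(plain, X))
  }
})

test_that("dense-link widths follow the concatenation wiring (2, 8, 14 for 3x4 units)", {
  spec <- dense_link_spec(3L, 4L, bidirectional = FALSE, input_dim = 2L)
  expect_equal(vapply(1:3, function(l) pdeeg:::dense_link_in_width(spec, l),
                      0L), c(2L, 8L, 14L))
  expect_equal(vapply(1:3, function(l) pdeeg:::dense_link_out_width(spec, l),
                      0L), c(6L, 6L, 6L))
  ps <- dense_link_params(spec, seed = 1L)
  out <- dense_link_forward(matrix(rnorm(10), 5), spec, ps)
  expect_equal(dim(out), c(5L, 6L))
  # width mismatches name the offending layer
  ps[[2]] <- lstm_params(5L, 4L, seed = 2L)
  expect_error(dense_link_forward(matrix(rnorm(10), 5), spec, ps),
               "layer 2")
})

test_that("the dense-linked stack matches a literal nested-loop transcription", {
  set.seed(76)
  for (bi in c(FALSE, TRUE)) {
    spec <- dense_link_spec(3L, 3L, bidirectional = bi, input_dim = 2L)
    ps <- dense_link_params(spec, seed = 11L)
    X <- matrix(rnorm(4 * 2), 4)
    got <- dense_link_forward(X, spec, ps)
    # oracle: explicit per-layer loops over the growing concatenation
    d_prev <- list(X)
    for (l in 1:3) {
      layer_in <- do.call(cbind, d_prev)
      H <- if (bi) oracle_bilstm_forward(layer_in, ps[[l]]) else
        oracle_lstm_forward(layer_in, ps[[l]])
      d_prev[[l + 1]] <- cbind(H, X)
    }
    expect_equal(got, d_prev[[4]], tolerance = 1e-12)
  }
})

test_that("cross-entropy matches the log-sum-exp oracle and its calibration points", {
  expect_equal(cross_entropy(matrix(c(0, 0), 1), matrix(c(1, 0), 1)),
               log(2))
  expect_equal(cross_entropy(matrix(c(0, 0), 1), matrix(c(0, 1), 1)),
               log(2))
  # huge true-class margin drives the loss to zero
  expect_lt(cross_entropy(matrix(c(20, 0), 1), matrix(c(1, 0), 1)), 1e-8)
  # uniform logits over N classes give log(N)
  for (N in c(2L, 3L, 5L)) {
    y <- matrix(0, 1, N)
    y[1, 2] <- 1
    expect_equal(cross_entropy(matrix(0, 1, N), y), log(N))
  }
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    k <- sample(2:4, 1)
    phi <- matrix(rnorm(n * k, sd = 3), n)
    y <- matrix(0, n, k)
    y[cbind(seq_len(n), sample(k, n, replace = TRUE))] <- 1
    oracle <- mean(vapply(seq_len(n), function(i) {
      -sum(y[i, ] * (phi[i, ] - log(sum(exp(phi[i, ])))))
    }, 0))
    got <- cross_entropy(phi, y)
    expect_lt(abs(got - oracle), 1e-12)
    expect_gte(got, 0)
  }
  expect_error(cross_entropy(matrix(0, 2, 2), matrix(c(1, 1, 1, 0), 2)),
               "one-hot")
})

test_that("fusion is exact on constants, full windows, and a brute-force enumeration", {
  E <- matrix(rep(c(0.3, 0.7), each = 6), 6)
  expect_equal(multiscale_fusion(E, c(1, 3, 5)), c(0.3, 0.7))
  set.seed(78)
  E2 <- matrix(runif(12), 6)
  expect_equal(multiscale_fusion(E2, 6L), colMeans(E2))
  # brute force over all windows for P = {2, 3}
  brute <- function(E, P) {
    per <- sapply(P, function(p) {
      wins <- sapply(1:(nrow(E) - p + 1), function(n) {
        colMeans(E[n:(n + p - 1), , drop = FALSE])
      })
      rowMeans(wins)
    })
    rowMeans(per)
  }
  expect_equal(multiscale_fusion(E2, c(2L, 3L)), brute(E2, c(2, 3)),
               tolerance = 1e-12)
  expect_error(multiscale_fusion(E2, 7L), "widths")
  # the literal printed normalization is available but not a fixed point
  lit <- multiscale_fusion(E2, 3L, literal = TRUE)
  expect_length(lit, 2L)
})
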