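# Model specification, presets, parameter accounting, and the batch
# forward/backward machinery.

test_that("the published layer stacks reproduce their consistent parameter counts", {
  t2 <- count_parameters("table2_dlblstm")$table
  expect_equal(t2$params[t2$type == "dense"], c(64L, 16448L, 130L))
  expect_equal(t2$params[t2$type == "bilstm"], 164864L)
  expect_equal(t2$params[t2$type == "batchnorm"], c(1024L, 256L))
  t3 <- count_parameters("table3_bilstm")$table
  expect_equal(t3$params[t3$type == "dense"], c(64L, 2080L, 130L))
  expect_equal(t3$params[t3$type == "bilstm"], c(16640L, 16640L))
  expect_equal(t3$params[t3$type == "batchnorm"], 256L)
  t1 <- count_parameters("table1_lstm")$table
  expect_equal(t1$params[t1$type == "lstm"][2], 12416L)
})

test_that("output shapes of the all-sequence preset match the printed column", {
  tab <- count_parameters("table3_bilstm")$table
  expect_equal(tab$output_shape,
               c("(None, 178, 1)", "(None, 178, 32)", "(None, 178, 64)",
                 "(None, 178, 64)", "(None, 178, 32)", "(None, 178, 64)",
                 "(None, 178, 64)", "(None, 178, 64)", "(None, 178, 2)"))
  t2 <- count_parameters("table2_dlblstm")$table
  expect_equal(t2$output_shape[3], "(None, 256)")   # non-sequence Bi-LSTM
  expect_equal(t2$output_shape[9], "(None, 2)")
})

test_that("counting rules evaluate the canonical single-layer cases", {
  one <- function(mk, in_feat, seq_len = 10L) {
    sp <- model_spec(layer_input(seq_len, in_feat), mk)
    count_parameters(sp)$table$params[2]
  }
  expect_equal(one(layer_bilstm(128L), 32L), 164864L)
  expect_equal(one(layer_lstm(32L), 64L), 12416L)
  expect_equal(one(layer_dense(2L), 64L), 130L)
  expect_equal(one(layer_batchnorm(), 256L), 1024L)
  expect_equal(one(layer_dropout(0.4), 7L), 0L)
})

test_that("totals are the sum of per-layer counts and specs are validated", {
  for (nm in c("table1_lstm", "table2_dlblstm", "table3_bilstm")) {
    cp <- count_parameters(nm)
    expect_identical(cp$total, sum(cp$table$params))
  }
  expect_error(model_spec(), "empty")
  expect_error(model_spec(layer_dense(3L)), "first layer")
  expect_error(model_preset("no_such"), "available")
  expect_error(layer_dropout(1.2), "rate")
  # recurrent layer after a non-sequence output is a structural error
  expect_error(model_spec(layer_input(4L, 3L),
                          layer_lstm(4L, return_sequence = FALSE),
                          layer_lstm(4L)), "sequence input")
})

test_that("describe_model renders the layer table with totals", {
  d <- describe_model("table2_dlblstm")
  expect_equal(nrow(d), 10L)
  expect_equal(d$params[3], "164,864")
  expect_equal(d$params[10], format(182786, big.mark = ","))
})

test_that("analytic gradients match finite differences through every layer type", {
  set.seed(42)
  B <- 3L; T_ <- 4L; F_ <- 3L
  x <- array(rnorm(B * T_ * F_), dim = c(B, T_, F_))
  y <- c(0L, 1L, 1L)
  spec <- model_spec(layer_input(T_, F_), layer_dense(3L, "relu"),
                     layer_bilstm(2L), layer_dropout(0),
                     layer_batchnorm(), layer_lstm(3L),
                     layer_dense(2L, activation = "softmax"))
  m <- build_model(spec, seed = 7L)
  loss_of <- function(mm) {
    fw <- pdeeg:::model_forward(mm, x, training = TRUE, output = "logit",
                                dropout_seed = 5L)
    pdeeg:::softmax_ce(pdeeg:::seq_to_mat(fw$out),
                       pdeeg:::replicate_labels(pdeeg:::one_hot(y), T_))$loss
  }
  fw <- pdeeg:::model_forward(m, x, training = TRUE, output = "logit",
                              dropout_seed = 5L)
  sc <- pdeeg:::softmax_ce(pdeeg:::seq_to_mat(fw$out),
                           pdeeg:::replicate_labels(pdeeg:::one_hot(y), T_))
  grads <- pdeeg:::model_backward(fw$model, fw$caches,
                                  pdeeg:::mat_to_seq(sc$grad, B, T_))
  eps <- 1e-6
  poke <- function(lst, path, i, d) {
    if (length(path) == 0L) {
      lst[i] <- lst[i] + d
      lst
    } else {
      lst[[path[1]]] <- poke(lst[[path[1]]], path[-1], i, d)
      lst
    }
  }
  worst <- 0
  cases <- list(list(2L, "W"), list(2L, "b"),
                list(3L, c("forward", "W_i")),
                list(3L, c("backward", "W_c")),
                list(3L, c("forward", "b_f")),
                list(5L, "gamma"), list(5L, "beta"),
                list(6L, "W_o"), list(6L, "b_c"),
                list(7L, "W"))
  for (case in cases) {
    k <- case[[1]]; path <- case[[2]]
    p <- m$layers[[k]]$params; g <- grads[[k]]
    for (nm in path) { p <- p[[nm]]; g <- g[[nm]] }
    for (i in sample(length(p), min(3L, length(p)))) {
      m2 <- m
      m2$layers[[k]]$params <- poke(m$layers[[k]]$params, path, i, eps)
      l1 <- loss_of(m2)
      m2$layers[[k]]$params <- poke(m$layers[[k]]$params, path, i, -eps)
      l0 <- loss_of(m2)
      worst <- max(worst, abs((l1 - l0) / (2 * eps) - g[i]))
    }
  }
  expect_lt(worst, 1e-7)
})

test_that("the batch LSTM forward agrees with the single-sequence reference", {
  set.seed(11)
  B <- 4L; T_ <- 6L; F_ <- 3L; U <- 5L
  x <- array(rnorm(B * T_ * F_), dim = c(B, T_, F_))
  p <- lstm_params(F_, U, seed = 2L)
  out <- pdeeg:::lstm_fwd_batch(x, p)$H3
  for (b in seq_len(B)) {
    ref <- lstm_forward(matrix(x[b, , ], T_, F_), p)
    expect_equal(matrix(out[b, , ], T_, U), ref, tolerance = 1e-12)
  }
})

test_that("the batch BiLSTM non-sequence head emits [h_f(T), h_b(1)]", {
  set.seed(12)
  B <- 2L; T_ <- 5L; F_ <- 3L; U <- 4L
  x <- array(rnorm(B * T_ * F_), dim = c(B, T_, F_))
  spec <- model_spec(layer_input(T_, F_),
                     layer_bilstm(U, return_sequence = FALSE))
  m <- build_model(spec, seed = 3L)
  out <- pdeeg:::model_forward(m, x)$out
  p <- m$layers[[2]]$params
  for (b in seq_len(B)) {
    ref <- bilstm_forward(matrix(x[b, , ], T_, F_),
                          structure(list(forward = p$forward,
                                         backward = p$backward),
                                    class = "bilstm_params"),
                          return_sequence = FALSE)
    expect_equal(out[b, ], ref, tolerance = 1e-12)
  }
})

test_that("dropout is the identity at inference; batchnorm uses running moments", {
  set.seed(13)
  x <- array(rnorm(2 * 3 * 4), dim = c(2L, 3L, 4L))
  spec <- model_spec(layer_input(3L, 4L), layer_dropout(0.5),
                     layer_batchnorm())
  m <- build_model(spec, seed = 1L)
  out1 <- pdeeg:::model_forward(m, x)$out
  out2 <- pdeeg:::model_forward(m, x)$out
  expect_identical(out1, out2)
  # fresh running moments are (0, 1): inference batchnorm is near-identity
  expect_equal(out1, x, tolerance = 1e-4)
  # training mode standardizes using the batch itself
  tr <- pdeeg:::model_forward(m, x, training = TRUE, dropout_seed = 2L)
  mcol <- colMeans(pdeeg:::seq_to_mat(tr$out))
  expect_lt(max(abs(mcol)), 1e-8)
})

test_that("predictions are softmax probabilities of the right shape", {
  set.seed(14)
  x <- array(rnorm(5 * 4 * 3), dim = c(5L, 4L, 3L))
  m_seq <- build_model(model_spec(layer_input(4L, 3L), layer_bilstm(2L),
                                  layer_dense(2L, "softmax")), seed = 2L)
  p_seq <- model_predict(m_seq, x)
  expect_equal(dim(p_seq), c(5L, 4L, 2L))
  expect_equal(apply(p_seq, c(1, 2), sum),
               matrix(1, 5, 4), tolerance = 1e-12)
  m_flat <- build_model(model_spec(layer_input(4L, 3L),
                                   layer_bilstm(2L, return_sequence = FALSE),
                                   layer_dense(2L, "softmax")), seed = 2L)
  p_flat <- model_predict(m_flat, x)
  expect_equal(dim(p_flat), c(5L, 2L))
  expect_equal(rowSums(p_flat), rep(1, 5), tolerance = 1e-12)
})
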