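# Declarative model construction: layer specs, the three printed-network
# presets, exact per-layer parameter accounting, initialization, and the
# batch forward pass used for training and inference.
#
# Parameter counting rule per layer type:
#   dense      units * (in + 1)
#   lstm       4 * (units * (in + units) + units)
#   bilstm     2 * the lstm count
#   batchnorm  4 * features  (scale, shift, and the two running-moment
#              vectors; only scale and shift receive gradient updates)
#   input, dropout  0

#' Layer constructors for a model specification
#'
#' @param seq_len input sequence length (time steps); `NA` accepts any.
#' @param features input feature width per step.
#' @param units layer width.
#' @param activation `"linear"`, `"relu"`, `"tanh"`, `"sigmoid"` or
#'   `"softmax"` (softmax only meaningful on the final dense layer).
#' @param return_sequence emit the full hidden sequence (recurrent layers).
#' @param rate dropout rate in `[0, 1)`.
#' @name model-layers
NULL

#' @rdname model-layers
#' @export
layer_input <- function(seq_len, features) {
  list(type = "input", seq_len = seq_len, features = as.integer(features))
}

#' @rdname model-layers
#' @export
layer_dense <- function(units, activation = "linear") {
  stopifnot(activation %in% c("linear", "relu", "tanh", "sigmoid", "softmax"))
  list(type = "dense", units = as.integer(units), activation = activation)
}

#' @rdname model-layers
#' @export
layer_lstm <- function(units, return_sequence = TRUE) {
  list(type = "lstm", units = as.integer(units),
       return_sequence = return_sequence)
}

#' @rdname model-layers
#' @export
layer_bilstm <- function(units, return_sequence = TRUE) {
  list(type = "bilstm", units = as.integer(units),
       return_sequence = return_sequence)
}

#' @rdname model-layers
#' @export
layer_dropout <- function(rate = 0.4) {
  if (rate < 0 || rate >= 1) fail_field("rate", "must lie in [0, 1)")
  list(type = "dropout", rate = rate)
}

#' @rdname model-layers
#' @export
layer_batchnorm <- function() list(type = "batchnorm")

#' Assemble a model specification
#'
#' An ordered layer list beginning with an input layer; consecutive layer
#' shapes are checked by walking the shape through the stack.
#'
#' @param ... layer specs (see [layer_input()] and friends), or a single
#'   list of them.
#' @param name optional label.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(..., name = "model") {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      is.null(layers[[1]]$type)) {
    layers <- layers[[1]]
  }
  if (length(layers) == 0L) stop("empty model spec", call. = FALSE)
  if (layers[[1]]$type != "input") {
    stop("the first layer must be an input layer", call. = FALSE)
  }
  spec <- structure(list(layers = layers, name = name), class = "model_spec")
  walk_shapes(spec)   # validates consecutive shapes
  spec
}

# Walk the (seq_len, features, is_seq) shape through the stack; returns a
# per-layer data.frame used by count_parameters and describe.
walk_shapes <- function(spec) {
  seq_len_cur <- spec$layers[[1]]$seq_len
  feat <- spec$layers[[1]]$features
  is_seq <- TRUE
  rows <- list()
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[[k]]
    in_feat <- feat
    if (k > 1L && ly$type %in% c("lstm", "bilstm") && !is_seq) {
      stop(sprintf("layer %d (%s): recurrent layer requires sequence input",
                   k, ly$type), call. = FALSE)
    }
    params <- switch(
      ly$type,
      input = 0L,
      dense = ly$units * (in_feat + 1L),
      lstm = 4L * (ly$units * (in_feat + ly$units) + ly$units),
      bilstm = 2L * 4L * (ly$units * (in_feat + ly$units) + ly$units),
      batchnorm = 4L * in_feat,
      dropout = 0L,
      stop(sprintf("unknown layer type '%s'", ly$type), call. = FALSE)
    )
    if (ly$type == "dense") feat <- ly$units
    if (ly$type == "lstm") {
      feat <- ly$units
      if (!ly$return_sequence) is_seq <- FALSE
    }
    if (ly$type == "bilstm") {
      feat <- 2L * ly$units
      if (!ly$return_sequence) is_seq <- FALSE
    }
    shape <- if (is_seq) {
      sprintf("(None, %s, %d)",
              ifelse(is.na(seq_len_cur), "T", seq_len_cur), feat)
    } else {
      sprintf("(None, %d)", feat)
    }
    rows[[k]] <- data.frame(layer = k, type = ly$type, output_shape = shape,
                            params = as.integer(params),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Count trainable parameters per layer
#'
#' Applies the per-layer counting rule (see package docs) and returns the
#' per-layer table plus the total; totals always equal the sum of per-layer
#' counts.
#'
#' @param spec a [model_spec()] or preset name (see [model_preset()]).
#' @return list with `table` (data.frame: layer, type, output_shape,
#'   params) and `total`.
#' @export
count_parameters <- function(spec) {
  if (is.character(spec)) spec <- model_preset(spec)
  tab <- walk_shapes(spec)
  list(table = tab, total = sum(tab$params))
}

#' Printed-architecture presets
#'
#' Three named presets reproduce the published layer stacks of the plain
#' LSTM, the single-bidirectional-block network, and the all-sequence
#' Bi-LSTM network, layer for layer (types and output shapes), for
#' parameter accounting and description. Note two published counts are
#' internally inconsistent with their printed shapes and are not
#' reproduced: the first LSTM layer of the plain-LSTM table (printed
#' 668,928, implying an undeclared input width) and its final dense layer
#' (printed 99 where a 32-to-2 dense has 66).
#'
#' @param name `"table1_lstm"`, `"table2_dlblstm"` or `"table3_bilstm"`.
#' @return a [model_spec()].
#' @export
model_preset <- function(name) {
  presets <- list(
    table1_lstm = function() model_spec(
      layer_input(1L, 64L),
      layer_lstm(64L, return_sequence = TRUE),
      layer_dropout(0.4),
      layer_lstm(32L, return_sequence = FALSE),
      layer_dropout(0.4),
      layer_dense(2L, activation = "softmax"),
      name = "table1_lstm"
    ),
    table2_dlblstm = function() model_spec(
      layer_input(178L, 1L),
      layer_dense(32L),
      layer_bilstm(128L, return_sequence = FALSE),
      layer_dropout(0.4),
      layer_batchnorm(),
      layer_dense(64L, activation = "relu"),
      layer_dropout(0.4),
      layer_batchnorm(),
      layer_dense(2L, activation = "softmax"),
      name = "table2_dlblstm"
    ),
    table3_bilstm = function() model_spec(
      layer_input(178L, 1L),
      layer_dense(32L),
      layer_bilstm(32L, return_sequence = TRUE),
      layer_dropout(0.4),
      layer_dense(32L),
      layer_bilstm(32L, return_sequence = TRUE),
      layer_dropout(0.4),
      layer_batchnorm(),
      layer_dense(2L, activation = "softmax"),
      name = "table3_bilstm"
    )
  )
  if (!name %in% names(presets)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]()
}

#' Scaled classifier spec for a given feature geometry
#'
#' The all-sequence Bi-LSTM preset rescaled to a data set's actual
#' sequence length and feature width, with all unit counts multiplied by
#' `scale` — the architecture used by the cross-validation experiments,
#' where full-size layers would be wasteful on small synthetic cohorts.
#'
#' @param seq_len,features input geometry.
#' @param scale multiplier on the preset's unit counts (default 0.25, i.e.
#'   dense 8 and Bi-LSTM 8 per direction).
#' @param dropout dropout rate.
#' @param two_blocks keep the second dense + Bi-LSTM block (default TRUE,
#'   mirroring the preset).
#' @return a [model_spec()].
#' @export
scaled_bilstm_spec <- function(seq_len, features, scale = 0.25,
                               dropout = 0.4, two_blocks = TRUE) {
  u <- max(2L, as.integer(round(32L * scale)))
  layers <- list(
    layer_input(as.integer(seq_len), as.integer(features)),
    layer_dense(u),
    layer_bilstm(u, return_sequence = TRUE),
    layer_dropout(dropout)
  )
  if (two_blocks) {
    layers <- c(layers, list(
      layer_dense(u),
      layer_bilstm(u, return_sequence = TRUE),
      layer_dropout(dropout)
    ))
  }
  layers <- c(layers, list(layer_batchnorm(),
                           layer_dense(2L, activation = "softmax")))
  model_spec(layers, name = sprintf("bilstm_scaled_%d", u))
}

#' Describe a model as a layer / shape / parameter table
#'
#' @param spec a [model_spec()] or preset name.
#' @return data.frame with one row per layer plus a total row; printed in
#'   the familiar model-summary style.
#' @export
describe_model <- function(spec) {
  cp <- count_parameters(spec)
  tab <- cp$table
  tab$params <- format(tab$params, big.mark = ",", trim = TRUE)
  out <- rbind(tab, data.frame(layer = NA, type = "total", output_shape = "",
                               params = format(cp$total, big.mark = ",",
                                               trim = TRUE)))
  out
}

# --- initialization ---------------------------------------------------------

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nrow = nr)
}

init_layer <- function(ly, in_feat, seed) {
  with_seed(seed, switch(
    ly$type,
    input = list(params = list(), state = list()),
    dropout = list(params = list(), state = list()),
    dense = list(params = list(W = glorot_mat(in_feat, ly$units),
                               b = numeric(ly$units)),
                 state = list()),
    batchnorm = list(params = list(gamma = rep(1, in_feat),
                                   beta = numeric(in_feat)),
                     state = list(running_mean = numeric(in_feat),
                                  running_var = rep(1, in_feat),
                                  momentum = 0.9, eps = 1e-5)),
    lstm = list(params = unclass(lstm_params(in_feat, ly$units,
                                             seed = stats::runif(1, 1, 1e8))),
                state = list()),
    bilstm = {
      seeds <- stats::runif(2, 1, 1e8)
      list(params = list(forward = unclass(lstm_params(in_feat, ly$units,
                                                       seeds[1])),
                         backward = unclass(lstm_params(in_feat, ly$units,
                                                        seeds[2]))),
           state = list())
    }
  ))
}

#' Build (initialize) a model from its specification
#'
#' Allocates and seeds every layer's parameters: Glorot-uniform weights,
#' zero biases except the LSTM forget bias (1), unit batch-norm scale.
#'
#' @param spec a [model_spec()] or preset name.
#' @param seed RNG seed for the weight draws.
#' @return an object of class `pdeeg_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (is.character(spec)) spec <- model_preset(spec)
  stopifnot(inherits(spec, "model_spec"))
  feat <- spec$layers[[1]]$features
  seeds <- derive_seeds(seed, length(spec$layers))
  layers <- vector("list", length(spec$layers))
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[[k]]
    layers[[k]] <- c(list(type = ly$type, spec = ly),
                     init_layer(ly, feat, seeds[k]))
    if (ly$type == "dense") feat <- ly$units
    if (ly$type == "lstm") feat <- ly$units
    if (ly$type == "bilstm") feat <- 2L * ly$units
  }
  structure(list(spec = spec, layers = layers, seed = as.integer(seed)),
            class = "pdeeg_model")
}

#' @export
print.pdeeg_model <- function(x, ...) {
  cat(sprintf("<pdeeg_model> %s\n", x$spec$name))
  print(describe_model(x$spec), row.names = FALSE)
  invisible(x)
}

# --- batch forward pass -----------------------------------------------------

# activations on batch data
apply_activation <- function(Z, activation) {
  switch(activation,
         linear = Z,
         relu = pmax(Z, 0),
         tanh = tanh(Z),
         sigmoid = sigmoid(Z),
         softmax = row_softmax(Z))
}

slice_t <- function(x3, t) {
  d <- dim(x3)
  matrix(x3[, t, ], nrow = d[1], ncol = d[3])
}

seq_to_mat <- function(x3) {
  d <- dim(x3)
  # rows ordered (batch fastest, then time); array() below inverts this
  matrix(x3, nrow = d[1] * d[2], ncol = d[3])
}

mat_to_seq <- function(m, b, t_len) array(m, dim = c(b, t_len, ncol(m)))

# LSTM over a batch: X3 is (B, T, F). Returns hidden sequence and the
# per-step cache needed for backpropagation through time.
lstm_fwd_batch <- function(X3, p, keep_cache = FALSE) {
  d <- dim(X3)
  B <- d[1]; T_len <- d[2]
  U <- p$units
  H3 <- array(0, dim = c(B, T_len, U))
  H <- matrix(0, B, U)
  C <- matrix(0, B, U)
  cache <- if (keep_cache) vector("list", T_len) else NULL
  tWi <- t(p$W_i); tWf <- t(p$W_f); tWo <- t(p$W_o); tWc <- t(p$W_c)
  for (t in seq_len(T_len)) {
    Z <- cbind(H, slice_t(X3, t))
    gi <- sigmoid(sweep(Z %*% tWi, 2L, p$b_i, `+`))
    gf <- sigmoid(sweep(Z %*% tWf, 2L, p$b_f, `+`))
    go <- sigmoid(sweep(Z %*% tWo, 2L, p$b_o, `+`))
    gc <- tanh(sweep(Z %*% tWc, 2L, p$b_c, `+`))
    C_prev <- C
    C <- gf * C_prev + gi * gc
    tc <- tanh(C)
    H <- go * tc
    H3[, t, ] <- H
    if (keep_cache) {
      cache[[t]] <- list(Z = Z, i = gi, f = gf, o = go, g = gc,
                         C_prev = C_prev, tc = tc)
    }
  }
  list(H3 = H3, cache = cache)
}

# BPTT for one direction. dH3 carries the upstream gradient on every
# hidden step (zeros where the step's output is unused).
lstm_bwd_batch <- function(dH3, cache, p) {
  d <- dim(dH3)
  B <- d[1]; T_len <- d[2]; U <- p$units
  F_in <- p$input_dim
  dX3 <- array(0, dim = c(B, T_len, F_in))
  g <- list(W_i = 0 * p$W_i, W_f = 0 * p$W_f, W_o = 0 * p$W_o,
            W_c = 0 * p$W_c, b_i = 0 * p$b_i, b_f = 0 * p$b_f,
            b_o = 0 * p$b_o, b_c = 0 * p$b_c)
  dh_next <- matrix(0, B, U)
  dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- slice_t(dH3, t) + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$C_prev
    dc_next <- dc * cc$f
    d_i <- di * cc$i * (1 - cc$i)
    d_f <- df * cc$f * (1 - cc$f)
    d_o <- do_ * cc$o * (1 - cc$o)
    d_g <- dg * (1 - cc$g^2)
    dZ <- d_i %*% p$W_i + d_f %*% p$W_f + d_o %*% p$W_o + d_g %*% p$W_c
    g$W_i <- g$W_i + t(d_i) %*% cc$Z
    g$W_f <- g$W_f + t(d_f) %*% cc$Z
    g$W_o <- g$W_o + t(d_o) %*% cc$Z
    g$W_c <- g$W_c + t(d_g) %*% cc$Z
    g$b_i <- g$b_i + colSums(d_i)
    g$b_f <- g$b_f + colSums(d_f)
    g$b_o <- g$b_o + colSums(d_o)
    g$b_c <- g$b_c + colSums(d_g)
    dh_next <- dZ[, seq_len(U), drop = FALSE]
    dX3[, t, ] <- dZ[, U + seq_len(F_in), drop = FALSE]
  }
  list(dX3 = dX3, grads = g)
}

rev_time <- function(x3) {
  x3[, rev(seq_len(dim(x3)[2])), , drop = FALSE]
}

# Forward through the whole stack. `training` enables dropout masks and
# batch statistics; `output` selects probabilities or raw logits at a
# softmax head. Returns activations, caches and updated batch-norm state.
model_forward <- function(model, X, training = FALSE,
                          output = c("prob", "logit"),
                          dropout_seed = NULL) {
  output <- match.arg(output)
  act <- X
  caches <- vector("list", length(model$layers))
  n_layers <- length(model$layers)
  drop_seeds <- if (training) {
    derive_seeds(dropout_seed %||% 1L, n_layers)
  } else NULL
  for (k in seq_len(n_layers)) {
    ly <- model$layers[[k]]
    sp <- ly$spec
    is_seq <- length(dim(act)) == 3L
    switch(
      ly$type,
      input = {
        if ((is_seq && dim(act)[3] != sp$features) ||
            (!is_seq && ncol(act) != sp$features)) {
          stop(sprintf("input feature width %d does not match spec %d",
                       if (is_seq) dim(act)[3] else ncol(act), sp$features),
               call. = FALSE)
        }
        caches[[k]] <- list()
      },
      dense = {
        m <- if (is_seq) seq_to_mat(act) else act
        Z <- sweep(m %*% ly$params$W, 2L, ly$params$b, `+`)
        a_fun <- sp$activation
        if (a_fun == "softmax" && (training || output == "logit")) {
          a_fun <- "linear"     # softmax folded into the loss / caller
        }
        A <- apply_activation(Z, a_fun)
        caches[[k]] <- list(input = m, Z = Z, is_seq = is_seq,
                            dims = dim(act))
        act <- if (is_seq) mat_to_seq(A, dim(act)[1], dim(act)[2]) else A
      },
      dropout = {
        if (training && sp$rate > 0) {
          mask <- with_seed(drop_seeds[k], {
            array(as.numeric(stats::runif(length(act)) >= sp$rate) /
                    (1 - sp$rate), dim = dim(act))
          })
          caches[[k]] <- list(mask = mask)
          act <- act * mask
        } else {
          caches[[k]] <- list(mask = NULL)
        }
      },
      batchnorm = {
        m <- if (is_seq) seq_to_mat(act) else act
        st <- ly$state
        if (training) {
          mu <- colMeans(m)
          v <- colMeans(sweep(m, 2L, mu)^2)
          st$running_mean <- st$momentum * st$running_mean +
            (1 - st$momentum) * mu
          st$running_var <- st$momentum * st$running_var +
            (1 - st$momentum) * v
          model$layers[[k]]$state <- st
        } else {
          mu <- st$running_mean
          v <- st$running_var
        }
        invstd <- 1 / sqrt(v + st$eps)
        xhat <- sweep(sweep(m, 2L, mu), 2L, invstd, `*`)
        A <- sweep(sweep(xhat, 2L, ly$params$gamma, `*`), 2L,
                   ly$params$beta, `+`)
        caches[[k]] <- list(xhat = xhat, invstd = invstd, is_seq = is_seq,
                            dims = dim(act))
        act <- if (is_seq) mat_to_seq(A, dim(act)[1], dim(act)[2]) else A
      },
      lstm = {
        fw <- lstm_fwd_batch(act, ly$params, keep_cache = training)
        caches[[k]] <- list(cache = fw$cache, dims = dim(act))
        act <- if (sp$return_sequence) fw$H3 else slice_t(fw$H3, dim(act)[2])
      },
      bilstm = {
        fwf <- lstm_fwd_batch(act, ly$params$forward, keep_cache = training)
        fwb <- lstm_fwd_batch(rev_time(act), ly$params$backward,
                              keep_cache = training)
        Hb <- rev_time(fwb$H3)    # backward hidden states in original time
        caches[[k]] <- list(cache_f = fwf$cache, cache_b = fwb$cache,
                            dims = dim(act))
        T_len <- dim(act)[2]
        if (sp$return_sequence) {
          U <- sp$units
          out <- array(0, dim = c(dim(act)[1], T_len, 2L * U))
          out[, , seq_len(U)] <- fwf$H3
          out[, , U + seq_len(U)] <- Hb
          act <- out
        } else {
          act <- cbind(slice_t(fwf$H3, T_len), slice_t(Hb, 1L))
        }
      }
    )
  }
  list(out = act, caches = caches, model = model)
}

#' Predict class probabilities
#'
#' Runs the model in inference mode (dropout off, batch-norm running
#' moments) and returns softmax probabilities: per time step for
#' sequence-output heads, per sample otherwise.
#'
#' @param model a built [build_model()] (typically trained).
#' @param X input batch: `(B, T, F)` array (or `(B, F)` matrix for
#'   non-sequence models).
#' @return array/matrix of class probabilities with the final dimension
#'   indexing classes (control, PD).
#' @export
model_predict <- function(model, X) {
  model_forward(model, X, training = FALSE, output = "prob")$out
}
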