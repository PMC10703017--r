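# Recurrent primitives built from first principles: the gated LSTM cell,
# bidirectional composition, and densely linked stacking with
# concatenation skip connections.
#
# Gate equations (per step, on the concatenation z = [h_{t-1}, x_t]):
#   i_t = sigmoid(W_i z + b_i)        input gate
#   f_t = sigmoid(W_f z + b_f)        forget gate
#   o_t = sigmoid(W_o z + b_o)        output gate
#   Chat = tanh(W_c z + b_c)          candidate cell state
#   c_t = f_t * c_{t-1} + i_t * Chat  cell state (elementwise)
#   h_t = o_t * tanh(c_t)             hidden state

#' LSTM parameter container
#'
#' Four gate weight matrices, each `units x (input_dim + units)`, acting on
#' the concatenation `[h_{t-1}, x_t]`, plus four bias vectors of length
#' `units`. Initialization is uniform Glorot-style (scaled by fan sum);
#' biases are zero except the forget-gate bias, set to 1 so early training
#' retains memory (the usual stability convention).
#'
#' @param input_dim input feature width.
#' @param units hidden state width.
#' @param seed RNG seed for the weight draw.
#' @param init `"glorot"` or `"zero"`.
#' @return an object of class `lstm_params`.
#' @export
lstm_params <- function(input_dim, units, seed = 1L,
                        init = c("glorot", "zero")) {
  init <- match.arg(init)
  fan <- input_dim + units
  draw <- function() {
    if (init == "zero") {
      matrix(0, nrow = units, ncol = fan)
    } else {
      lim <- sqrt(6 / (fan + units))
      matrix(stats::runif(units * fan, -lim, lim), nrow = units)
    }
  }
  with_seed(seed, {
    structure(
      list(W_i = draw(), W_f = draw(), W_o = draw(), W_c = draw(),
           b_i = numeric(units), b_f = rep(if (init == "zero") 0 else 1,
                                           units),
           b_o = numeric(units), b_c = numeric(units),
           input_dim = as.integer(input_dim), units = as.integer(units)),
      class = "lstm_params"
    )
  })
}

#' Zero LSTM state
#'
#' @param units hidden width.
#' @return list with `h` and `c`, both zero vectors of length `units`.
#' @export
lstm_state <- function(units) {
  list(h = numeric(units), c = numeric(units))
}

#' One LSTM cell step
#'
#' Applies the gate equations to a single input vector and carries the
#' cell/hidden state forward. All three gates are sigmoid outputs in
#' (0, 1); the hidden state is the output gate times `tanh` of the cell
#' state, hence bounded by 1 in absolute value.
#'
#' @param x_t input vector of length `input_dim`.
#' @param state list with `h` and `c` (see [lstm_state()]).
#' @param params an [lstm_params()].
#' @return the new state: list with `h`, `c`.
#' @export
lstm_cell_step <- function(x_t, state, params) {
  if (length(x_t) != params$input_dim) {
    stop(sprintf("input has length %d, expected %d", length(x_t),
                 params$input_dim), call. = FALSE)
  }
  if (!all(is.finite(x_t)) || !all(is.finite(state$h)) ||
      !all(is.finite(state$c))) {
    stop("non-finite input or state in lstm_cell_step", call. = FALSE)
  }
  z <- c(state$h, x_t)
  i <- sigmoid(as.vector(params$W_i %*% z) + params$b_i)
  f <- sigmoid(as.vector(params$W_f %*% z) + params$b_f)
  o <- sigmoid(as.vector(params$W_o %*% z) + params$b_o)
  chat <- tanh(as.vector(params$W_c %*% z) + params$b_c)
  c_new <- f * state$c + i * chat
  list(h = o * tanh(c_new), c = c_new)
}

#' Run an LSTM over a sequence
#'
#' Iterates [lstm_cell_step()] from the zero state over the rows of `X`.
#'
#' @param X `T x input_dim` matrix (one row per time step).
#' @param params an [lstm_params()].
#' @param return_sequence if `TRUE`, return the full `T x units` hidden
#'   sequence; otherwise the final hidden vector.
#' @return matrix or vector of hidden states.
#' @export
lstm_forward <- function(X, params, return_sequence = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("empty sequence", call. = FALSE)
  state <- lstm_state(params$units)
  H <- matrix(0, nrow = nrow(X), ncol = params$units)
  for (t in seq_len(nrow(X))) {
    state <- lstm_cell_step(X[t, ], state, params)
    H[t, ] <- state$h
  }
  if (return_sequence) H else H[nrow(X), ]
}

#' Bidirectional LSTM parameters
#'
#' @param input_dim input feature width (shared by both directions).
#' @param units hidden width per direction.
#' @param seed RNG seed (forward and backward draws are derived from it).
#' @return an object of class `bilstm_params` with elements `forward` and
#'   `backward`.
#' @export
bilstm_params <- function(input_dim, units, seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  structure(
    list(forward = lstm_params(input_dim, units, seeds[1]),
         backward = lstm_params(input_dim, units, seeds[2]),
         input_dim = as.integer(input_dim), units = as.integer(units)),
    class = "bilstm_params"
  )
}

#' Run a bidirectional LSTM over a sequence
#'
#' The forward pass runs `t = 1..T`; the backward pass runs `t = T..1`
#' with state flowing from `t + 1`. With `return_sequence`, each step's
#' output is the concatenation `[h_f(t), h_b(t)]` (width `2 * units`);
#' otherwise the output is `[h_f(T), h_b(1)]`, the final step of each
#' direction.
#'
#' @param X `T x input_dim` matrix.
#' @param params a [bilstm_params()].
#' @param return_sequence return the full `T x 2*units` sequence or the
#'   `2*units` end-state concatenation.
#' @return matrix or vector.
#' @export
bilstm_forward <- function(X, params, return_sequence = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("empty sequence", call. = FALSE)
  Hf <- lstm_forward(X, params$forward, return_sequence = TRUE)
  Hb_rev <- lstm_forward(X[rev(seq_len(nrow(X))), , drop = FALSE],
                         params$backward, return_sequence = TRUE)
  Hb <- Hb_rev[rev(seq_len(nrow(X))), , drop = FALSE]
  if (return_sequence) cbind(Hf, Hb) else c(Hf[nrow(X), ], Hb[1, ])
}

#' Densely linked stack specification
#'
#' Describes an `L`-layer recurrent stack in which layer `l` receives, at
#' every time step, the concatenation of the raw input and the outputs of
#' all preceding layers (`d^0 = x_t`), and emits
#' `d^l = [h^l, x_t]` — concatenation skip connections rather than
#' additive residuals.
#'
#' @param n_layers number of recurrent layers `L >= 1`.
#' @param units hidden width per layer (recycled to length `n_layers`).
#' @param bidirectional use bidirectional layers (`h^l` has width
#'   `2 * units`).
#' @param input_dim raw input feature width.
#' @return an object of class `dense_link_spec`.
#' @export
dense_link_spec <- function(n_layers, units, bidirectional = FALSE,
                            input_dim) {
  if (n_layers < 1L) fail_field("n_layers", "must be >= 1")
  units <- rep_len(as.integer(units), n_layers)
  structure(
    list(n_layers = as.integer(n_layers), units = units,
         bidirectional = bidirectional, input_dim = as.integer(input_dim)),
    class = "dense_link_spec"
  )
}

# Width of d^l = [h^l, x_t] for layer l.
dense_link_out_width <- function(spec, l) {
  spec$units[l] * (if (spec$bidirectional) 2L else 1L) + spec$input_dim
}

# Input width of layer l: the raw input plus all preceding d^m.
dense_link_in_width <- function(spec, l) {
  w <- spec$input_dim
  if (l > 1L) {
    w <- w + sum(vapply(seq_len(l - 1L),
                        function(m) dense_link_out_width(spec, m), 0L))
  }
  w
}

#' Initialize parameters for a densely linked stack
#'
#' @param spec a [dense_link_spec()].
#' @param seed RNG seed.
#' @return list of per-layer [lstm_params()] or [bilstm_params()].
#' @export
dense_link_params <- function(spec, seed = 1L) {
  seeds <- derive_seeds(seed, spec$n_layers)
  lapply(seq_len(spec$n_layers), function(l) {
    in_w <- dense_link_in_width(spec, l)
    if (spec$bidirectional) bilstm_params(in_w, spec$units[l], seeds[l])
    else lstm_params(in_w, spec$units[l], seeds[l])
  })
}

#' Forward pass through a densely linked (bi)LSTM stack
#'
#' Layer `l` at step `t` consumes `[d^0_t, d^1_t, ..., d^{l-1}_t]`
#' (with `d^0 = x_t`), produces `h^l_t` via its (bi)LSTM, and emits
#' `d^l_t = [h^l_t, x_t]`. With a single layer this reduces exactly to the
#' plain (bi)LSTM output concatenated with the input.
#'
#' @param X `T x input_dim` matrix.
#' @param spec a [dense_link_spec()].
#' @param all_params list of per-layer parameters
#'   (see [dense_link_params()]).
#' @return `T x width_L` matrix, the last layer's `d^L` sequence.
#' @export
dense_link_forward <- function(X, spec, all_params) {
  X <- as.matrix(X)
  if (ncol(X) != spec$input_dim) {
    stop(sprintf("input width %d does not match spec input_dim %d",
                 ncol(X), spec$input_dim), call. = FALSE)
  }
  d_list <- list(X)     # d^0 = x_t
  for (l in seq_len(spec$n_layers)) {
    layer_in <- do.call(cbind, d_list)
    p <- all_params[[l]]
    expected <- dense_link_in_width(spec, l)
    actual_in <- if (spec$bidirectional) p$input_dim else p$input_dim
    if (ncol(layer_in) != expected || actual_in != expected) {
      stop(sprintf("layer %d: input width %d does not match expected %d",
                   l, ncol(layer_in), expected), call. = FALSE)
    }
    H <- if (spec$bidirectional) {
      bilstm_forward(layer_in, p, return_sequence = TRUE)
    } else {
      lstm_forward(layer_in, p, return_sequence = TRUE)
    }
    d_list[[l + 1L]] <- cbind(H, X)          # d^l = [h^l, x_t]
  }
  d_list[[spec$n_layers + 1L]]
}

#' Categorical cross-entropy from logits
#'
#' Mean over rows of the negative log-softmax of the true class,
#' `logsumexp(phi) - phi_true`, computed with max-subtraction
#' stabilization. Always nonnegative; equals `log(N)` for uniform logits
#' over `N` classes.
#'
#' @param logits `rows x N_classes` score matrix.
#' @param labels one-hot matrix of the same shape (exactly one 1 per row).
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(logits, labels) {
  logits <- as.matrix(logits)
  labels <- as.matrix(labels)
  if (ncol(logits) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (!identical(dim(logits), dim(labels))) {
    stop("logits and labels must have identical shape", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1)) || !all(rowSums(labels) == 1)) {
    stop("labels must be one-hot (exactly one 1 per row)", call. = FALSE)
  }
  lse <- row_logsumexp(logits)
  mean(lse - rowSums(labels * logits))
}

#' Multi-scale sliding-window score fusion
#'
#' Combines per-step class scores into a single score vector: for each
#' window width `p`, every length-`p` window `[n, n + p)` of rows of `E`
#' is averaged, the window averages are averaged, and the final output is
#' the mean over widths. Constant score sequences are fixed points, and a
#' single full-length window reduces to the column mean. The raw printed
#' normalization (`1/((T-p) p)` over windows `n = 1..T-p` of `p + 1`
#' steps) is available behind `literal = TRUE` for comparison.
#'
#' @param E `T x N_classes` matrix of per-step scores.
#' @param widths vector of window widths, each in `[1, T]`.
#' @param literal use the raw printed normalization instead of the
#'   mean-of-window-means reading.
#' @return fused score vector of length `N_classes`.
#' @export
multiscale_fusion <- function(E, widths = c(1L, 3L, 5L), literal = FALSE) {
  E <- as.matrix(E)
  T_len <- nrow(E)
  widths <- as.integer(widths)
  if (any(widths < 1L) || any(widths > T_len)) {
    stop(sprintf("window widths must lie in [1, %d]", T_len), call. = FALSE)
  }
  per_width <- vapply(widths, function(p) {
    if (literal) {
      if (T_len - p < 1L) stop("literal form needs p < T", call. = FALSE)
      acc <- numeric(ncol(E))
      for (n in seq_len(T_len - p)) {
        acc <- acc + colSums(E[n:(n + p), , drop = FALSE])
      }
      acc / ((T_len - p) * p)
    } else {
      n_win <- T_len - p + 1L
      acc <- numeric(ncol(E))
      for (n in seq_len(n_win)) {
        acc <- acc + colMeans(E[n:(n + p - 1L), , drop = FALSE])
      }
      acc / n_win
    }
  }, numeric(ncol(E)))
  rowMeans(as.matrix(per_width))
}
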