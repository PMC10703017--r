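# Gradient-based training: backpropagation through the layer stack
# (including backpropagation through time for both LSTM directions),
# softmax cross-entropy loss, Adam updates, early stopping on validation
# loss with best-epoch restoration.

#' Training configuration
#'
#' Defaults follow the tuned hyperparameter set: learning rate 0.001,
#' batch size 64, 20 epochs, dropout 0.4 (set in the model spec), Adam.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param dropout dropout rate recorded for provenance (the active rate
#'   lives in the model spec's dropout layers).
#' @param optimizer only `"adam"` is implemented.
#' @param patience early-stopping patience in epochs on validation loss;
#'   `Inf` disables early stopping.
#' @param seed RNG seed for shuffling and dropout masks.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         epochs = 20L, dropout = 0.4, optimizer = "adam",
                         patience = 5L, seed = 1L) {
  cfg <- structure(list(learning_rate = learning_rate,
                        batch_size = as.integer(batch_size),
                        epochs = as.integer(epochs), dropout = dropout,
                        optimizer = optimizer, patience = patience,
                        seed = as.integer(seed)),
                   class = "train_config")
  if (cfg$learning_rate < 0) fail_field("learning_rate", "must be >= 0")
  if (cfg$batch_size < 1L) fail_field("batch_size", "must be >= 1")
  if (cfg$epochs < 1L) fail_field("epochs", "must be >= 1")
  if (cfg$optimizer != "adam") fail_field("optimizer", "only 'adam' is implemented")
  cfg
}

# loss and gradient at a softmax head, from logits
softmax_ce <- function(logits_m, Y_m) {
  p <- row_softmax(logits_m)
  loss <- mean(row_logsumexp(logits_m) - rowSums(Y_m * logits_m))
  list(loss = loss, grad = (p - Y_m) / nrow(logits_m))
}

one_hot <- function(y, n_classes = 2L) {
  Y <- matrix(0, nrow = length(y), ncol = n_classes)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

# Backward pass mirroring model_forward; returns per-layer gradient lists
# (same structure as each layer's params).
model_backward <- function(model, caches, dOut) {
  n_layers <- length(model$layers)
  grads <- vector("list", n_layers)
  dAct <- dOut
  for (k in rev(seq_len(n_layers))) {
    ly <- model$layers[[k]]
    sp <- ly$spec
    cc <- caches[[k]]
    switch(
      ly$type,
      input = {
        grads[[k]] <- list()
      },
      dense = {
        dm <- if (cc$is_seq) seq_to_mat(dAct) else dAct
        act_fun <- sp$activation
        dZ <- switch(act_fun,
                     linear = dm,
                     softmax = dm,     # folded into the loss gradient
                     relu = dm * (cc$Z > 0),
                     tanh = dm * (1 - tanh(cc$Z)^2),
                     sigmoid = {
                       s <- sigmoid(cc$Z)
                       dm * s * (1 - s)
                     })
        grads[[k]] <- list(W = t(cc$input) %*% dZ, b = colSums(dZ))
        dIn <- dZ %*% t(ly$params$W)
        dAct <- if (cc$is_seq) mat_to_seq(dIn, cc$dims[1], cc$dims[2]) else dIn
      },
      dropout = {
        grads[[k]] <- list()
        if (!is.null(cc$mask)) dAct <- dAct * cc$mask
      },
      batchnorm = {
        dm <- if (cc$is_seq) seq_to_mat(dAct) else dAct
        m_rows <- nrow(dm)
        dgamma <- colSums(dm * cc$xhat)
        dbeta <- colSums(dm)
        dxhat <- sweep(dm, 2L, ly$params$gamma, `*`)
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * cc$xhat)
        dIn <- sweep(
          (dxhat - matrix(s1 / m_rows, m_rows, length(s1), byrow = TRUE) -
             cc$xhat * matrix(s2 / m_rows, m_rows, length(s2), byrow = TRUE)),
          2L, cc$invstd, `*`)
        grads[[k]] <- list(gamma = dgamma, beta = dbeta)
        dAct <- if (cc$is_seq) mat_to_seq(dIn, cc$dims[1], cc$dims[2]) else dIn
      },
      lstm = {
        dims <- cc$dims
        U <- sp$units
        if (sp$return_sequence) {
          dH3 <- dAct
        } else {
          dH3 <- array(0, dim = c(dims[1], dims[2], U))
          dH3[, dims[2], ] <- dAct
        }
        bw <- lstm_bwd_batch(dH3, cc$cache, ly$params)
        grads[[k]] <- bw$grads
        dAct <- bw$dX3
      },
      bilstm = {
        dims <- cc$dims
        U <- sp$units
        if (sp$return_sequence) {
          dHf3 <- dAct[, , seq_len(U), drop = FALSE]
          dHb3_rev <- rev_time(dAct[, , U + seq_len(U), drop = FALSE])
        } else {
          dHf3 <- array(0, dim = c(dims[1], dims[2], U))
          dHf3[, dims[2], ] <- dAct[, seq_len(U), drop = FALSE]
          dHb3_rev <- array(0, dim = c(dims[1], dims[2], U))
          # the reversed-time run's last step is the original t = 1
          dHb3_rev[, dims[2], ] <- dAct[, U + seq_len(U), drop = FALSE]
        }
        bwf <- lstm_bwd_batch(dHf3, cc$cache_f, ly$params$forward)
        bwb <- lstm_bwd_batch(dHb3_rev, cc$cache_b, ly$params$backward)
        grads[[k]] <- list(forward = bwf$grads, backward = bwb$grads)
        dAct <- bwf$dX3 + rev_time(bwb$dX3)
      }
    )
  }
  grads
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like)
  else if (is.numeric(p)) p * 0
  else p
}

# One Adam step on a (possibly nested) parameter list.
adam_step <- function(params, grads, m, v, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  if (is.list(params)) {
    for (nm in names(params)) {
      if (is.list(params[[nm]]) || is.numeric(params[[nm]])) {
        if (!is.null(grads[[nm]])) {
          res <- adam_step(params[[nm]], grads[[nm]], m[[nm]], v[[nm]],
                           lr, t, beta1, beta2, eps)
          params[[nm]] <- res$params
          m[[nm]] <- res$m
          v[[nm]] <- res$v
        }
      }
    }
    return(list(params = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  params <- params - lr * mhat / (sqrt(vhat) + eps)
  list(params = params, m = m, v = v)
}

# Replicate one-hot labels across time steps in seq_to_mat row order
# (batch index varies fastest).
replicate_labels <- function(Y, t_len) {
  Y[rep(seq_len(nrow(Y)), times = t_len), , drop = FALSE]
}

# loss/accuracy of a model on a labelled set (inference mode)
eval_model <- function(model, x, y) {
  fw <- model_forward(model, x, training = FALSE, output = "logit")
  logits <- fw$out
  Y <- one_hot(y)
  if (length(dim(logits)) == 3L) {
    lm <- seq_to_mat(logits)
    sc <- softmax_ce(lm, replicate_labels(Y, dim(logits)[2]))
    probs3 <- mat_to_seq(row_softmax(lm), dim(logits)[1], dim(logits)[2])
    pmean <- apply(probs3, c(1, 3), mean)
  } else {
    sc <- softmax_ce(logits, Y)
    pmean <- row_softmax(logits)
  }
  pred <- max.col(pmean, ties.method = "first") - 1L
  list(loss = sc$loss, acc = mean(pred == y), prob = pmean)
}

#' Train a model
#'
#' Minimizes the softmax cross-entropy of the classifier over minibatches
#' with Adam. For sequence-output heads every time step carries its
#' segment's label and the loss averages over steps. Validation loss is
#' monitored each epoch; training stops once it fails to improve for
#' `patience` consecutive epochs and the best-epoch parameters are
#' restored. Fully seeded: identical seeds, data and configuration give
#' identical training trajectories.
#'
#' @param model a [build_model()] result.
#' @param train_data list with `x` (`(B, T, F)` array or `(B, F)` matrix)
#'   and `y` (integer labels, 0 = control / 1 = PD).
#' @param val_data optional list like `train_data` used for early
#'   stopping; when `NULL`, training runs all epochs.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `model` (trained) and `history` (data.frame: epoch,
#'   train_loss, train_acc, val_loss, val_acc).
#' @export
train <- function(model, train_data, val_data = NULL, cfg = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "pdeeg_model"))
  x <- train_data$x
  y <- as.integer(train_data$y)
  n <- if (length(dim(x)) == 3L) dim(x)[1] else nrow(x)
  if (n < 1L) stop("empty training set", call. = FALSE)
  Y <- one_hot(y)
  adam_m <- lapply(model$layers, function(l) zeros_like(l$params))
  adam_v <- adam_m
  step <- 0L
  n_batches <- ceiling(n / cfg$batch_size)
  batch_seeds <- matrix(derive_seeds(cfg$seed, cfg$epochs * n_batches * 2L),
                        ncol = 2L)
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  wait <- 0L
  history <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- with_seed(cfg$seed + epoch, sample.int(n))
    for (b in seq_len(n_batches)) {
      idx <- order_idx[((b - 1L) * cfg$batch_size + 1L):
                         min(b * cfg$batch_size, n)]
      xb <- if (length(dim(x)) == 3L) {
        x[idx, , , drop = FALSE]
      } else {
        x[idx, , drop = FALSE]
      }
      Yb <- Y[idx, , drop = FALSE]
      srow <- (epoch - 1L) * n_batches + b
      fw <- model_forward(model, xb, training = TRUE, output = "logit",
                          dropout_seed = batch_seeds[srow, 1])
      model <- fw$model          # commit batch-norm running moments
      logits <- fw$out
      if (length(dim(logits)) == 3L) {
        sc <- softmax_ce(seq_to_mat(logits),
                         replicate_labels(Yb, dim(logits)[2]))
        dOut <- mat_to_seq(sc$grad, dim(logits)[1], dim(logits)[2])
      } else {
        sc <- softmax_ce(logits, Yb)
        dOut <- sc$grad
      }
      if (!is.finite(sc$loss)) {
        stop(sprintf("training diverged (loss %g) at epoch %d batch %d",
                     sc$loss, epoch, b), call. = FALSE)
      }
      grads <- model_backward(model, fw$caches, dOut)
      step <- step + 1L
      for (k in seq_along(model$layers)) {
        if (length(model$layers[[k]]$params) == 0L) next
        res <- adam_step(model$layers[[k]]$params, grads[[k]],
                         adam_m[[k]], adam_v[[k]], cfg$learning_rate, step)
        model$layers[[k]]$params <- res$params
        adam_m[[k]] <- res$m
        adam_v[[k]] <- res$v
      }
    }
    tr <- eval_model(model, x, y)
    va <- if (!is.null(val_data)) {
      eval_model(model, val_data$x, as.integer(val_data$y))
    } else {
      list(loss = NA_real_, acc = NA_real_)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tr$loss, train_acc = tr$acc,
      val_loss = va$loss, val_acc = va$acc))
    if (verbose) {
      message(sprintf("epoch %2d  train loss %.4f acc %.3f  val loss %s acc %s",
                      epoch, tr$loss, tr$acc,
                      ifelse(is.na(va$loss), "-", sprintf("%.4f", va$loss)),
                      ifelse(is.na(va$acc), "-", sprintf("%.3f", va$acc))))
    }
    if (!is.null(val_data)) {
      if (va$loss < best$loss - 1e-10) {
        best <- list(loss = va$loss, layers = model$layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (!is.null(val_data) && is.finite(best$loss)) {
    model$layers <- best$layers
  }
  list(model = model, history = history)
}

#' Fuse per-segment scores into one prediction per subject
#'
#' Concatenates a subject's per-step positive/negative class probabilities
#' across all their segments into one score sequence and applies
#' [multiscale_fusion()]; the fused positive-class probability is
#' thresholded at 0.5.
#'
#' @param model trained model with a sequence or flat softmax head.
#' @param x feature array for the segments (`(B, T, F)`).
#' @param subject_ids per-segment subject identifiers.
#' @param widths fusion window widths (clipped to each subject's sequence
#'   length).
#' @return data.frame with `subject_id`, `score` (fused positive-class
#'   probability) and `pred` (0/1).
#' @export
subject_scores <- function(model, x, subject_ids, widths = c(1L, 3L, 5L)) {
  probs <- model_predict(model, x)
  is_seq <- length(dim(probs)) == 3L
  subjects <- unique(subject_ids)
  out <- lapply(subjects, function(sid) {
    rows <- which(subject_ids == sid)
    E <- if (is_seq) {
      do.call(rbind, lapply(rows, function(i) {
        matrix(probs[i, , ], ncol = dim(probs)[3])
      }))
    } else {
      probs[rows, , drop = FALSE]
    }
    w <- pmin(widths, nrow(E))
    fused <- multiscale_fusion(E, unique(w))
    data.frame(subject_id = sid, score = fused[2],
               pred = as.integer(fused[2] > 0.5),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
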