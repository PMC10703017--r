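# Evaluation protocol: stratified 80-10-10 split, stratified k-fold plans,
# and subject-level cross-validation of the full classifier.

#' Stratified 80-10-10 train / validation / test split
#'
#' Partitions the subjects into disjoint, exhaustive train, validation and
#' test sets with `|val| = |test| = floor(0.1 n)` and the remainder in
#' train, allocating per class by largest remainder so each part's class
#' mix tracks the cohort's. Deterministic given the seed.
#'
#' @param subjects character vector of subject ids.
#' @param labels 0/1 labels, parallel to `subjects`.
#' @param seed RNG seed.
#' @return list with `train`, `val`, `test` (character vectors of ids).
#' @export
split_80_10_10 <- function(subjects, labels, seed = 1L) {
  n <- length(subjects)
  stopifnot(length(labels) == n)
  if (n < 3L) stop("need at least 3 subjects to split", call. = FALSE)
  n_test <- floor(0.1 * n)
  n_val <- floor(0.1 * n)
  classes <- sort(unique(labels))
  # per-class quotas by largest remainder
  quota <- function(total) {
    raw <- vapply(classes, function(cl) total * sum(labels == cl) / n, 0)
    base <- floor(raw)
    rem <- total - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    base
  }
  q_test <- quota(n_test)
  q_val <- quota(n_val)
  parts <- list(train = character(), val = character(), test = character())
  for (ci in seq_along(classes)) {
    ids <- subjects[labels == classes[ci]]
    ids <- with_seed(seed + ci, sample(ids))
    k1 <- q_test[ci]
    k2 <- q_val[ci]
    parts$test <- c(parts$test, ids[seq_len(k1)])
    parts$val <- c(parts$val, ids[k1 + seq_len(k2)])
    rest <- if (k1 + k2 > 0L) ids[-seq_len(k1 + k2)] else ids
    parts$train <- c(parts$train, rest)
  }
  for (cl in classes) {
    if (!any(subjects[labels == cl] %in% parts$train)) {
      stop(sprintf("class %s absent from the training split", cl),
           call. = FALSE)
    }
  }
  parts
}

#' Stratified k-fold plan
#'
#' Assigns subjects to `k` folds so that each fold's class counts differ
#' by at most one from proportionality: within each class, subjects are
#' shuffled (seeded) and dealt out `floor(n_class / k)` per fold, with the
#' remainder going to the currently smallest folds. Deterministic given
#' the seed.
#'
#' @param subjects character vector of subject ids.
#' @param labels 0/1 labels, parallel to `subjects`.
#' @param k fold count (default 6).
#' @param seed RNG seed.
#' @return an object of class `fold_plan`: list with `k`, `assignment`
#'   (integer fold per subject, named), `seed`, `level`.
#' @export
stratified_kfold <- function(subjects, labels, k = 6L, seed = 1L) {
  n <- length(subjects)
  stopifnot(length(labels) == n)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds the %d available subjects", k, n),
                  call. = FALSE)
  assignment <- integer(n)
  names(assignment) <- subjects
  fold_sizes <- integer(k)
  classes <- sort(unique(labels))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- with_seed(seed + ci, sample(idx))
    n_c <- length(idx)
    base <- n_c %/% k
    rem <- n_c %% k
    per_fold <- rep(base, k)
    if (rem > 0) {
      # give the extras to the currently smallest folds (ties by index)
      ord <- order(fold_sizes, seq_len(k))
      per_fold[ord[seq_len(rem)]] <- per_fold[ord[seq_len(rem)]] + 1L
    }
    at <- 0L
    for (f in seq_len(k)) {
      take <- per_fold[f]
      if (take > 0) {
        assignment[idx[at + seq_len(take)]] <- f
        at <- at + take
      }
    }
    fold_sizes <- fold_sizes + per_fold
  }
  if (any(tabulate(assignment, k) == 0L)) {
    stop("fold plan produced an empty fold; reduce k", call. = FALSE)
  }
  structure(list(k = k, assignment = assignment, seed = as.integer(seed),
                 level = "subject"),
            class = "fold_plan")
}

# Standardize feature arrays per feature column using statistics from the
# training rows only (leakage-safe).
standardize_features <- function(x_train, x_other = NULL) {
  d <- dim(x_train)
  m_train <- matrix(x_train, nrow = d[1] * d[2], ncol = d[3])
  mu <- colMeans(m_train)
  sdv <- pmax(apply(m_train, 2L, stats::sd), 1e-8)
  scale_arr <- function(x) {
    dd <- dim(x)
    m <- matrix(x, nrow = dd[1] * dd[2], ncol = dd[3])
    m <- sweep(sweep(m, 2L, mu), 2L, sdv, `/`)
    array(m, dim = dd)
  }
  list(train = scale_arr(x_train),
       other = if (!is.null(x_other)) scale_arr(x_other) else NULL,
       mean = mu, sd = sdv)
}

subject_label_map <- function(subject_ids, y) {
  subs <- unique(subject_ids)
  lab <- vapply(subs, function(s) {
    ys <- unique(y[subject_ids == s])
    if (length(ys) != 1L) {
      stop(sprintf("subject %s has inconsistent labels", s), call. = FALSE)
    }
    as.integer(ys)
  }, 0L)
  names(lab) <- subs
  lab
}

#' Cross-validate the classifier
#'
#' Runs stratified k-fold cross-validation of the full classifier on
#' precomputed feature sequences. The default unit of splitting is the
#' subject, which guarantees no individual contributes segments to both a
#' training and a test fold; `level = "segment"` splits segments directly
#' (the leakage-prone protocol, kept for comparison). Per fold: an inner
#' stratified validation slice is carved from the training units for
#' early stopping, features are standardized with training-fold statistics
#' only, a fresh seeded model is trained, and the held-out units are
#' scored — subjects via [subject_scores()] (multi-scale fusion of their
#' segments' per-step class scores), segments via their own fused scores.
#'
#' @param dataset list with `x` (`(B, T, F)` feature array), `y`
#'   (per-segment 0/1 labels) and `subject_ids` (per-segment provenance),
#'   as produced by [segments_to_features()].
#' @param spec a [model_spec()] (or function of `(seq_len, features)`
#'   returning one) for the classifier.
#' @param cfg a [train_config()].
#' @param k number of folds (default 6).
#' @param level `"subject"` (default, leakage-safe) or `"segment"`.
#' @param widths fusion window widths.
#' @param permute_labels permute subject labels (seeded) before planning
#'   folds — a null-model control that should yield chance accuracy.
#' @param seed seed for fold planning, permutation and per-fold model
#'   initialization.
#' @param verbose print per-fold progress.
#' @return list with `folds` (per-fold `metrics_report` plus `auc`),
#'   `summary` (data.frame of mean and sd per metric), `plan`, `level`.
#' @export
cross_validate <- function(dataset, spec, cfg = train_config(), k = 6L,
                           level = c("subject", "segment"),
                           widths = c(1L, 3L, 5L), permute_labels = FALSE,
                           seed = 1L, verbose = FALSE) {
  level <- match.arg(level)
  x <- dataset$x
  y <- as.integer(dataset$y)
  subject_ids <- dataset$subject_ids
  if (permute_labels) {
    sub_lab <- subject_label_map(subject_ids, y)
    perm <- with_seed(seed + 7919L, sample(unname(sub_lab)))
    names(perm) <- names(sub_lab)
    y <- unname(perm[subject_ids])
  }
  units <- if (level == "subject") unique(subject_ids) else
    as.character(seq_along(y))
  unit_of <- if (level == "subject") subject_ids else
    as.character(seq_along(y))
  unit_labels <- if (level == "subject") {
    unname(subject_label_map(subject_ids, y)[units])
  } else {
    y
  }
  plan <- stratified_kfold(units, unit_labels, k = k, seed = seed)
  fold_seeds <- derive_seeds(seed, k * 2L)
  folds <- vector("list", k)
  evaluated_units <- character()
  for (f in seq_len(k)) {
    test_units <- units[plan$assignment == f]
    train_units <- units[plan$assignment != f]
    test_lab <- unit_labels[plan$assignment == f]
    if (length(unique(test_lab)) < 2L) {
      stop(sprintf("fold %d contains a single class; cannot evaluate", f),
           call. = FALSE)
    }
    # inner validation slice from the training units, for early stopping
    tr_lab <- unit_labels[plan$assignment != f]
    val_units <- character()
    for (cl in unique(tr_lab)) {
      ids <- train_units[tr_lab == cl]
      # keep at least one training unit per class
      n_val <- if (length(ids) >= 2L) max(1L, length(ids) %/% 6L) else 0L
      if (n_val > 0L) {
        val_units <- c(val_units,
                       with_seed(fold_seeds[k + f], sample(ids, n_val)))
      }
    }
    core_units <- setdiff(train_units, val_units)
    sel <- function(us) which(unit_of %in% us)
    i_tr <- sel(core_units)
    i_va <- sel(val_units)
    i_te <- sel(test_units)
    std <- standardize_features(x[i_tr, , , drop = FALSE])
    apply_std <- function(xa) {
      dd <- dim(xa)
      m <- matrix(xa, nrow = dd[1] * dd[2], ncol = dd[3])
      m <- sweep(sweep(m, 2L, std$mean), 2L, std$sd, `/`)
      array(m, dim = dd)
    }
    mspec <- if (is.function(spec)) spec(dim(x)[2], dim(x)[3]) else spec
    model <- build_model(mspec, seed = fold_seeds[f])
    cfg_f <- cfg
    cfg_f$seed <- fold_seeds[f]
    val_data <- if (length(i_va) > 0L) {
      list(x = apply_std(x[i_va, , , drop = FALSE]), y = y[i_va])
    }
    fit <- train(model, list(x = std$train, y = y[i_tr]), val_data, cfg_f)
    if (level == "subject") {
      sc <- subject_scores(fit$model, apply_std(x[i_te, , , drop = FALSE]),
                           subject_ids[i_te], widths = widths)
      truth <- unit_labels[match(sc$subject_id, units)]
      scores <- sc$score
      preds <- sc$pred
    } else {
      sc <- subject_scores(fit$model, apply_std(x[i_te, , , drop = FALSE]),
                           as.character(i_te), widths = widths)
      truth <- y[i_te][match(sc$subject_id, as.character(i_te))]
      scores <- sc$score
      preds <- sc$pred
    }
    rep_f <- compute_metrics(confusion_from_predictions(preds, truth))
    rep_f$auc <- if (length(unique(truth)) == 2L) {
      roc_auc(scores, truth)$auc
    } else {
      NA_real_
    }
    folds[[f]] <- rep_f
    evaluated_units <- c(evaluated_units, test_units)
    if (verbose) {
      message(sprintf("fold %d/%d: accuracy %.3f (n = %d)", f, k,
                      rep_f$accuracy, length(test_units)))
    }
  }
  stopifnot(setequal(evaluated_units, units),
            length(evaluated_units) == length(units))
  metric_names <- c("accuracy", "precision", "recall", "specificity",
                    "f1", "auc")
  vals <- sapply(metric_names, function(mn) {
    vapply(folds, function(fl) fl[[mn]] %||% NA_real_, 0)
  })
  summary <- data.frame(metric = metric_names,
                        mean = colMeans(vals, na.rm = TRUE),
                        sd = apply(vals, 2L, stats::sd, na.rm = TRUE),
                        row.names = NULL)
  list(folds = folds, summary = summary, plan = plan, level = level)
}
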