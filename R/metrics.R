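# Classification metrics: confusion matrix, accuracy / precision / recall /
# specificity / F1, and rank-based ROC AUC.

#' Confusion matrix
#'
#' @param tp,tn,fp,fn nonnegative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    fail_field("counts", "must be nonnegative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from predictions
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels (1 = PD, the positive class).
#' @return a [confusion_matrix()].
#' @export
confusion_from_predictions <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  confusion_matrix(tp = sum(pred == 1 & truth == 1),
                   tn = sum(pred == 0 & truth == 0),
                   fp = sum(pred == 1 & truth == 0),
                   fn = sum(pred == 0 & truth == 1))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("control", "PD"),
                              predicted = c("control", "PD")))
  print(m)
  invisible(x)
}

#' Compute the classification metric suite from a confusion matrix
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 (harmonic mean of
#' precision and recall). A metric whose denominator is zero is reported
#' as 0 and listed in the `undefined` field rather than raising an error.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report`: list with `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`, `confusion`, `undefined`
#'   (character vector of flagged metrics) and `per_class` (the same
#'   ratios with the control class treated as positive).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  undefined <- character()
  ratio <- function(num, den, nm) {
    if (den == 0) {
      undefined <<- c(undefined, nm)
      0
    } else {
      num / den
    }
  }
  precision <- ratio(cm$tp, cm$tp + cm$fp, "precision")
  recall <- ratio(cm$tp, cm$tp + cm$fn, "recall")
  specificity <- ratio(cm$tn, cm$tn + cm$fp, "specificity")
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  # control-as-positive view (per-class breakdown)
  prec0 <- if (cm$tn + cm$fn == 0) 0 else cm$tn / (cm$tn + cm$fn)
  rec0 <- if (cm$tn + cm$fp == 0) 0 else cm$tn / (cm$tn + cm$fp)
  f10 <- if (prec0 + rec0 == 0) 0 else 2 * prec0 * rec0 / (prec0 + rec0)
  structure(
    list(accuracy = (cm$tp + cm$tn) / total, precision = precision,
         recall = recall, specificity = specificity, f1 = f1,
         confusion = cm, undefined = undefined,
         per_class = data.frame(
           class = c("control", "PD"),
           precision = c(prec0, precision),
           recall = c(rec0, recall),
           # with control as positive, the negatives are the PD cases
           specificity = c(recall, specificity),
           f1 = c(f10, f1))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f  precision %.4f  recall %.4f  specificity %.4f  F1 %.4f\n",
    x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  if (length(x$undefined)) {
    cat("  (reported as 0, zero denominator:",
        paste(x$undefined, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' ROC curve and AUC by the rank (pairwise comparison) formulation
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with ties counted half — computed from average ranks, which
#' is exactly the mean over all positive/negative pairs. Curve points are
#' returned at every distinct score threshold.
#'
#' @param scores positive-class scores or probabilities.
#' @param labels true 0/1 labels; both classes must be present.
#' @return list with `auc` and `curve` (data.frame: threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  r <- rank(scores)                       # average ranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thresholds),
    fpr = c(0, vapply(thresholds,
                      function(th) sum(scores >= th & labels == 0L) / n0, 0)),
    tpr = c(0, vapply(thresholds,
                      function(th) sum(scores >= th & labels == 1L) / n1, 0)))
  list(auc = auc, curve = curve)
}
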