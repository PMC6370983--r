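# ROC AUC (Mann-Whitney convention) and operating-point metrics.

#' ROC AUC via the Mann-Whitney statistic
#'
#' Over all positive-negative pairs a higher positive score counts 1, a tie
#' counts 0.5, divided by `n_pos * n_neg`. Errors when only one class is
#' present (AUC undefined).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels of the same length.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_named("roc_auc: length mismatch")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_named("roc_auc: undefined, need both classes (got %d positive, %d negative)", n_pos, n_neg)
  }
  r <- rank(scores)  # average ranks implement the half-credit tie rule
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at an operating point
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy; a metric
#' whose denominator is zero is reported as `NA` (undefined), never 0.
#'
#' @param preds integer 0/1 predictions.
#' @param labels integer 0/1 reference labels.
#' @return An `evaluation_result` list with fields `accuracy`, `sensitivity`,
#'   `specificity`, `tp`, `fp`, `tn`, `fn` (and `auc = NA`, fillable by the
#'   caller).
#' @export
confusion_metrics <- function(preds, labels) {
  if (length(preds) != length(labels)) stop_named("confusion_metrics: length mismatch")
  preds <- as.integer(preds); labels <- as.integer(labels)
  tp <- sum(preds == 1L & labels == 1L)
  fp <- sum(preds == 1L & labels == 0L)
  tn <- sum(preds == 0L & labels == 0L)
  fn <- sum(preds == 0L & labels == 1L)
  structure(list(
    auc = NA_real_,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "evaluation_result")
}

#' Evaluate scores against labels at a threshold
#'
#' Convenience wrapper combining [roc_auc()] and [confusion_metrics()] at
#' `score >= threshold`.
#'
#' @param scores numeric scores; `labels` 0/1 labels.
#' @param labels integer 0/1 labels.
#' @param threshold operating threshold (default 0.5).
#' @return An `evaluation_result`.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  res <- confusion_metrics(binarize(scores, threshold), labels)
  res$auc <- roc_auc(scores, labels)
  res
}

#' Arithmetic mean of metrics over folds
#'
#' @param per_fold non-empty list of `evaluation_result`s.
#' @return An `evaluation_result` whose numeric fields are fold means.
#' @export
mean_over_folds <- function(per_fold) {
  if (length(per_fold) == 0L) stop_named("mean_over_folds: empty input")
  fields <- c("auc", "accuracy", "sensitivity", "specificity",
              "tp", "fp", "tn", "fn")
  out <- lapply(fields, function(f) {
    mean(vapply(per_fold, function(r) as.numeric(r[[f]] %||% NA_real_), 0))
  })
  names(out) <- fields
  structure(out, class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation: AUC %.3f, acc %.3f, sens %.3f, spec %.3f>\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}
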