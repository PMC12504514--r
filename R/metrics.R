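#' AUROC by the rank statistic
#'
#' Mann-Whitney form of the area under the ROC curve: average ranks of the
#' positive scores (ties counted one half, via midranks). Equals brute-force
#' enumeration of all (positive, negative) pairs.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics report
#'
#' Accuracy, positive-class precision/recall/F1 at a fixed probability
#' threshold, AUC by the rank statistic, and the confusion counts.
#'
#' @param scores Predicted probabilities.
#' @param labels Binary labels.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `"metrics_report"`.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(precision) && is.finite(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 auc = auc_rank(scores, labels),
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 threshold = threshold, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  accuracy %.3f  recall %.3f  F1 %.3f  AUC %s\n",
              x$n, x$accuracy, x$recall, x$f1,
              if (is.na(x$auc)) "NA (single class)" else sprintf("%.3f", x$auc)))
  invisible(x)
}
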