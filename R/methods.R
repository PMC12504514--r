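#' @export
print.akinet <- function(x, ...) {
  dims <- attr(x$params, "dims")
  cat(sprintf("AKI risk model (%s mode%s)\n", x$mode,
              if (x$mode == "pooled" && !x$attention) ", no attention" else ""))
  cat(sprintf("  encoder: LSTM d = %d -> d_h = %d; attention width %d\n",
              dims$d, dims$d_h, dims$d_a))
  cat(sprintf("  trained %d epochs (SGD, lr0 = %g); best epoch %d, validation AUC %.3f\n",
              nrow(x$logs), x$train$lr0, x$best_epoch, x$best_val_auc))
  cat(sprintf("  cohort: %d patients (train %d / val %d / test %d)\n",
              x$cohort$n, length(x$splits$train), length(x$splits$val),
              length(x$splits$test)))
  invisible(x)
}

#' @export
summary.akinet <- function(object, ...) {
  test <- cohort_subset(object$cohort, object$splits$test)
  pred <- predict(object, test, type = "patient")
  truth <- vapply(test$profiles, function(p) p$outcome_aki, 1L)
  m <- evaluate_predictions(pred, truth)
  out <- list(model = object, test_metrics = m,
              last_log = utils::tail(object$logs, 1L))
  class(out) <- "summary.akinet"
  out
}

#' @export
print.summary.akinet <- function(x, ...) {
  print(x$model)
  cat("held-out test split: ")
  print(x$test_metrics)
  invisible(x)
}

#' @export
coef.akinet <- function(object, ...) flatten_params(object$params)

#' Predict AKI risk for new patients
#'
#' New cohorts are imputed and normalised with the training-split statistics
#' stored in the fit, padded, and run through the trained network.
#'
#' @param object A fitted [akinet()] model.
#' @param newdata An [aki_cohort()]; defaults to the fit's held-out test
#'   split.
#' @param type `"patient"` (one risk per patient: the attention-pooled risk
#'   in pooled mode, the maximum per-step risk in sequence mode), `"step"`
#'   (per-step probabilities, sequence mode), `"tasks"` (the three outcome
#'   heads), or `"attention"` (per-step attention weights, pooled mode).
#' @param ... Unused.
#' @return A numeric vector, matrix, or list of per-step vectors.
#' @export
predict.akinet <- function(object, newdata = NULL,
                           type = c("patient", "step", "tasks", "attention"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- cohort_subset(object$cohort, object$splits$test)
  batch <- prepare_batch(object, newdata)
  res <- akinet_loss_grad(object$params, batch, loss_config(), object$mode,
                          attention = object$attention)
  d_h <- attr(object$params, "dims")$d_h
  if (type == "patient") {
    if (object$mode == "sequence")
      return(patient_scores(res$fitted, batch$pad_mask))
    return(res$fitted)
  }
  if (type == "step") {
    if (object$mode != "sequence") stop("per-step risks require sequence mode")
    return(lapply(seq_len(nrow(res$fitted)), function(b)
      res$fitted[b, seq_len(batch$lengths[b])]))
  }
  if (type == "attention") {
    if (is.null(res$alpha)) stop("attention weights require pooled mode with attention")
    return(lapply(seq_len(nrow(res$alpha)), function(b)
      res$alpha[b, seq_len(batch$lengths[b])]))
  }
  # tasks: heads on the shared representation
  cache <- lstm_forward(object$params, batch)
  shared <- if (object$mode == "pooled" && object$attention && !is.null(res$alpha)) {
    S <- matrix(0, nrow(res$alpha), d_h)
    for (t in seq_len(ncol(res$alpha))) S <- S + res$alpha[, t] * cache$H[[t]]
    S
  } else {
    t(vapply(seq_along(batch$lengths), function(b)
      cache$H[[batch$lengths[b]]][b, ], numeric(d_h)))
  }
  multitask_forward(shared, object$params)
}

# impute/normalise/pad a cohort with the fit's stored training statistics
prepare_batch <- function(object, cohort) {
  co <- impute_cohort(cohort, object$preprocess)
  co <- normalize_cohort(co, object$stats)
  build_batch(co, T_max = max(object$T_max,
                              vapply(co$series, series_length, 1L)))
}

#' @export
residuals.akinet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- cohort_subset(object$cohort, object$splits$test)
  pred <- predict(object, newdata, type = "patient")
  truth <- vapply(newdata$profiles, function(p) p$outcome_aki, 1L)
  truth - pred
}

#' Training-curve plot
#'
#' @param x A fitted [akinet()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.akinet <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$logs$epoch, x$logs$total, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss",
                 main = "composite objective", ...)
  graphics::plot(x$logs$epoch, x$logs$val_auc, type = "b", pch = 16,
                 xlab = "epoch", ylab = "validation AUC",
                 main = "validation AUC", ylim = c(0.4, 1))
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
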