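# Flat per-step logistic predictor: the no-sequence ablation. Replaces the
# recurrent encoder with a single affine layer applied to each step's
# (flattened) input features, trained by the same SGD schedule on the masked
# per-step cross-entropy.
flat_fit <- function(batch, val_batch, train) {
  d <- dim(batch$inputs)[3]
  w <- numeric(d); b <- 0
  n <- dim(batch$inputs)[1]
  best <- list(auc = -Inf, w = w, b = b)
  with_seed(train$seed + 1L, {
    for (epoch in seq_len(train$epochs)) {
      lr <- lr_schedule(epoch - 1L, train$lr0, train$decay_factor,
                        train$decay_every)
      order_idx <- sample(n)
      for (s in seq(1L, n, by = train$batch_size)) {
        idx <- order_idx[s:min(s + train$batch_size - 1L, n)]
        X <- batch$inputs[idx, , , drop = FALSE]
        M <- batch$pad_mask[idx, , drop = FALSE]
        Y <- batch$labels[idx, , drop = FALSE]
        B <- length(idx); T_len <- dim(X)[2]
        gw <- numeric(d); gb <- 0
        for (t in seq_len(T_len)) {
          X_t <- matrix(X[, t, ], nrow = B)
          p <- stats::plogis(drop(X_t %*% w) + b)
          dz <- (p - Y[, t]) * M[, t] / B
          gw <- gw + drop(crossprod(X_t, dz))
          gb <- gb + sum(dz)
        }
        w <- w - lr * gw; b <- b - lr * gb
      }
      vp <- flat_predict(w, b, val_batch)
      auc <- auc_rank(vp, val_batch$outcomes[, 1L])
      if (is.finite(auc) && auc > best$auc) best <- list(auc = auc, w = w, b = b)
    }
  })
  if (!is.finite(best$auc)) best <- list(auc = NA_real_, w = w, b = b)
  best
}

flat_predict <- function(w, b, batch) {
  B <- dim(batch$inputs)[1]; T_len <- dim(batch$inputs)[2]
  P <- matrix(0, B, T_len)
  for (t in seq_len(T_len))
    P[, t] <- stats::plogis(drop(matrix(batch$inputs[, t, ], nrow = B) %*% w) + b)
  patient_scores(P, batch$pad_mask)
}

#' Component ablations on matched splits and seeds
#'
#' Re-runs the experiment with specific components excluded or replaced by
#' simpler alternatives, on the same split and seed as the baseline:
#' \describe{
#'   \item{`no_sequence`}{the recurrent encoder is replaced by a flat
#'     per-step affine predictor (no temporal dependencies);}
#'   \item{`no_attention`}{pooled mode keeps the LSTM backbone but predicts
#'     from the final hidden state instead of the attention pool;}
#'   \item{`no_generalization`}{class-imbalance handling, the smoothness
#'     penalty and the attention-entropy regulariser are all disabled.}
#' }
#'
#' @param cohort A labelled [aki_cohort()].
#' @param switches Character vector of ablation switches (see above);
#'   default runs all three plus the baseline.
#' @param mode Prediction mode for the baseline.
#' @param loss,train,resample,preprocess Passed to [akinet()].
#' @param filter Apply cohort filters first.
#' @return Data frame of held-out test metrics, one row per configuration
#'   (baseline first).
#' @export
ablate <- function(cohort,
                   switches = c("no_sequence", "no_attention",
                                "no_generalization"),
                   mode = "pooled", loss = loss_config(),
                   train = train_config(), resample = NULL,
                   preprocess = preprocess_config(), filter = TRUE) {
  bad <- setdiff(switches, c("no_sequence", "no_attention", "no_generalization"))
  if (length(bad)) stop("unknown ablation switch: ", paste(bad, collapse = ", "))

  run_metrics <- function(fit) {
    test <- cohort_subset(fit$cohort, fit$splits$test)
    pred <- predict(fit, test, type = "patient")
    truth <- vapply(test$profiles, function(p) p$outcome_aki, 1L)
    m <- evaluate_predictions(pred, truth)
    data.frame(accuracy = m$accuracy, recall = m$recall, f1 = m$f1,
               auc = m$auc)
  }

  base <- akinet(cohort, mode = mode, loss = loss, train = train,
                 resample = resample, preprocess = preprocess,
                 filter = filter)
  rows <- list(cbind(config = "baseline", run_metrics(base)))

  for (sw in switches) {
    row <- switch(sw,
      no_attention = {
        fit <- akinet(cohort, mode = "pooled", loss = loss, train = train,
                      resample = resample, preprocess = preprocess,
                      filter = filter, attention = FALSE)
        cbind(config = sw, run_metrics(fit))
      },
      no_generalization = {
        l2 <- loss
        l2$smooth_gamma <- 0; l2$entropy_beta <- 0
        l2$data_loss <- "bce"; l2$class_weights <- NULL
        fit <- akinet(cohort, mode = mode, loss = l2, train = train,
                      resample = NULL, preprocess = preprocess,
                      filter = filter)
        cbind(config = sw, run_metrics(fit))
      },
      no_sequence = {
        # reuse the baseline's split and preprocessing for a matched design
        co <- base$cohort
        prep <- function(idx) {
          sub <- cohort_subset(co, idx)
          build_batch(normalize_cohort(impute_cohort(sub, preprocess),
                                       base$stats), base$T_max)
        }
        tr <- prep(base$splits$train)
        va <- prep(base$splits$val)
        te <- prep(base$splits$test)
        f <- flat_fit(tr, va, train)
        pred <- flat_predict(f$w, f$b, te)
        m <- evaluate_predictions(pred, te$outcomes[, 1L])
        data.frame(config = sw, accuracy = m$accuracy, recall = m$recall,
                   f1 = m$f1, auc = m$auc)
      })
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
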