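#' Training configuration
#'
#' Plain stochastic gradient descent with a stepped learning-rate decay:
#' the rate starts at `lr0` and is divided by `decay_factor` every
#' `decay_every` epochs.
#'
#' @param lr0 Initial learning rate (default 0.001).
#' @param decay_factor Decay divisor (default 10).
#' @param decay_every Epochs between decays (default 10).
#' @param batch_size Mini-batch size (default 32).
#' @param epochs Training epochs (default 50).
#' @param split Train/validation/test fractions (default 80/10/10; use
#'   `c(0.70, 0.15, 0.15)` for small cohorts).
#' @param seed Seed governing the split, initialisation and batch order.
#' @param d_h,d_a Hidden and attention widths passed to [akinet_params()].
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(lr0 = 0.001, decay_factor = 10, decay_every = 10L,
                         batch_size = 32L, epochs = 50L,
                         split = c(0.8, 0.1, 0.1), seed = 1L,
                         d_h = 64L, d_a = 32L) {
  stopifnot(lr0 >= 0, abs(sum(split) - 1) < 1e-8, length(split) == 3L)
  structure(list(lr0 = lr0, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), split = split,
                 seed = as.integer(seed), d_h = as.integer(d_h),
                 d_a = as.integer(d_a)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' `lr(epoch) = lr0 * decay_factor^(-floor(epoch / decay_every))` with
#' 0-based epochs.
#'
#' @param epoch 0-based epoch index.
#' @param lr0,decay_factor,decay_every Schedule constants.
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, lr0 = 0.001, decay_factor = 10,
                        decay_every = 10L) {
  stopifnot(all(epoch >= 0))
  lr0 * decay_factor^(-floor(epoch / decay_every))
}

#' Seeded patient-level data split
#'
#' @param n Patient count.
#' @param split Fractions for train/validation/test.
#' @param seed RNG seed.
#' @return List of index vectors `train`, `val`, `test` (disjoint, exact to
#'   within one patient of the requested fractions).
#' @export
split_cohort <- function(n, split = c(0.8, 0.1, 0.1), seed = 1L) {
  with_seed(seed, {
    idx <- sample(n)
    n_train <- floor(split[1] * n)
    n_val <- floor(split[2] * n)
    out <- list(train = sort(idx[seq_len(n_train)]),
                val = sort(idx[n_train + seq_len(n_val)]),
                test = sort(idx[(n_train + n_val + 1):n]))
  })
  out
}

#' Build model-ready arrays from a preprocessed cohort
#'
#' Pads and masks the sequences ([pad_and_mask()]) and attaches the static
#' design matrix (used as the attention context) and the three patient
#' outcome columns.
#'
#' @param cohort An imputed, normalised [aki_cohort()].
#' @param T_max Padded length (default: longest series).
#' @return A `padded_batch` with extra fields `static` and `outcomes`.
#' @export
build_batch <- function(cohort, T_max = NULL) {
  pb <- pad_and_mask(cohort$series, T_max)
  pb$static <- profile_matrix(cohort$profiles)
  pb$outcomes <- do.call(rbind, lapply(cohort$profiles, function(p)
    c(p$outcome_aki, p$outcome_recovery, p$outcome_dialysis)))
  pb
}

slice_batch <- function(batch, idx) {
  structure(list(inputs = batch$inputs[idx, , , drop = FALSE],
                 pad_mask = batch$pad_mask[idx, , drop = FALSE],
                 labels = batch$labels[idx, , drop = FALSE],
                 lengths = batch$lengths[idx],
                 channels = batch$channels,
                 static = batch$static[idx, , drop = FALSE],
                 outcomes = batch$outcomes[idx, , drop = FALSE]),
            class = "padded_batch")
}

# per-patient score from per-step probabilities: the risk at the final real
# step, i.e. the model's current risk estimate at the end of the observation
# window (which is anchored at onset for positives, end of record otherwise)
patient_scores <- function(P, pad_mask) {
  vapply(seq_len(nrow(P)), function(b) {
    real <- which(pad_mask[b, ])
    P[b, real[length(real)]]
  }, 1.0)
}

#' Fit the AKI risk model
#'
#' The front end of the package: takes a labelled cohort, applies the
#' inclusion filters, splits by patient, imputes and normalises with
#' training-split statistics only, optionally rebalances the training split,
#' and trains the LSTM(-attention) network by plain SGD on the composite
#' objective. Two prediction modes are available: `"sequence"` (a risk
#' probability at every hourly step, trained on the per-step KDIGO labels)
#' and `"pooled"` (one attention-pooled risk per patient, trained on the
#' patient outcome). The best-validation-AUC parameters are retained.
#'
#' @param cohort A labelled [aki_cohort()].
#' @param mode `"sequence"` or `"pooled"`.
#' @param loss A [loss_config()].
#' @param train A [train_config()].
#' @param resample Optional [resampling_plan()] applied to the training
#'   split only (or `TRUE` for a balanced-to-50% default plan).
#' @param preprocess A [preprocess_config()].
#' @param filter Apply [apply_cohort_filters()] first (default `TRUE`).
#' @param augment Re-augment the training sequences every epoch
#'   ([augment_series()]); training only, never validation.
#' @param dynamic_weights Update class weights each epoch from per-class
#'   training accuracy ([dynamic_weight_update()]); combined
#'   multiplicatively with any static class weights and renormalised to
#'   mean 1 (only meaningful with the weighted data term).
#' @param attention Pooled mode only: `FALSE` gives the no-attention
#'   ablation (final hidden state in place of the attention pool).
#' @param verbose Print a one-line log per epoch.
#' @return An object of class `"akinet"`.
#' @export
akinet <- function(cohort, mode = c("sequence", "pooled"),
                   loss = loss_config(), train = train_config(),
                   resample = NULL, preprocess = preprocess_config(),
                   filter = TRUE, augment = FALSE, dynamic_weights = FALSE,
                   attention = TRUE, verbose = FALSE) {
  mode <- match.arg(mode)
  call <- match.call()
  if (filter) {
    f <- apply_cohort_filters(cohort)
    cohort <- f$cohort
    exclusions <- f$report
  } else exclusions <- NULL
  if (cohort$n < 10L) stop("too few patients after filtering")

  splits <- split_cohort(cohort$n, train$split, train$seed)
  train_cohort <- cohort_subset(cohort, splits$train)

  if (isTRUE(resample)) {
    n_pos <- sum(vapply(train_cohort$profiles, function(p) p$outcome_aki, 1L))
    resample <- resampling_plan(n_pos, train_cohort$n - n_pos,
                                target_prevalence = 0.5, seed = train$seed)
  }
  if (!is.null(resample))
    train_cohort <- hybrid_resample(train_cohort, resample, preprocess)$cohort

  # preprocessing statistics from the training split only
  imp_cfg <- preprocess
  train_imp <- impute_cohort(train_cohort, imp_cfg)
  stats <- channel_stats(train_imp)
  prep <- function(co) {
    normalize_cohort(impute_cohort(co, imp_cfg, stats_cohort = train_cohort),
                     stats)
  }
  T_max <- max(vapply(cohort$series, series_length, 1L),
               vapply(train_cohort$series, series_length, 1L))
  train_norm <- prep(train_cohort)
  train_batch <- build_batch(train_norm, T_max)
  val_batch <- build_batch(prep(cohort_subset(cohort, splits$val)), T_max)

  d <- cohort$d
  params <- akinet_params(d, d_h = train$d_h, d_a = train$d_a,
                          p_static = ncol(train_batch$static),
                          seed = train$seed)
  n_train <- train_norm$n
  logs <- list()
  best <- list(auc = -Inf, params = params, epoch = 0L)
  eff_loss <- loss
  dyn_w <- c(1, 1)
  diverged <- FALSE

  with_seed(train$seed + 1L, {
    for (epoch in seq_len(train$epochs)) {
      if (diverged) break
      lr <- lr_schedule(epoch - 1L, train$lr0, train$decay_factor,
                        train$decay_every)
      if (augment) {
        aug <- train_norm
        aug$series <- lapply(aug$series, augment_series, config = preprocess,
                             channel_meta = aug$channel_meta)
        epoch_batch <- build_batch(aug, T_max)
      } else epoch_batch <- train_batch
      order_idx <- sample(n_train)
      starts <- seq(1L, n_train, by = train$batch_size)
      epoch_loss <- c(data_term = 0, l2_term = 0, smooth_term = 0,
                      entropy_term = 0, multitask_term = 0, total = 0)
      for (s in starts) {
        idx <- order_idx[s:min(s + train$batch_size - 1L, n_train)]
        mb <- slice_batch(epoch_batch, idx)
        res <- akinet_loss_grad(params, mb, eff_loss, mode,
                                attention = attention)
        if (!is.finite(res$breakdown$total)) {
          warning(sprintf("non-finite loss at epoch %d; stopping with last good parameters",
                          epoch))
          diverged <- TRUE
          break
        }
        params <- params_axpy(params, res$grads, -lr)
        for (nm in names(epoch_loss)) if (!is.null(res$breakdown[[nm]]))
          epoch_loss[nm] <- epoch_loss[nm] + res$breakdown[[nm]] * length(idx)
      }
      if (diverged) break
      epoch_loss <- epoch_loss / n_train

      val <- predict_batch(params, val_batch, mode, attention)
      vm <- evaluate_predictions(val$patient, val_batch$outcomes[, 1L])
      if (dynamic_weights && eff_loss$data_loss == "weighted") {
        tr <- predict_batch(params, epoch_batch, mode, attention)
        acc <- class_accuracies(tr, epoch_batch, mode)
        dyn_w <- dynamic_weight_update(acc, eff_loss$dynamic_temp)
        base_w <- loss$class_weights %||% c(1, 1)
        w <- base_w * dyn_w
        eff_loss$class_weights <- w / mean(w)
      }
      logs[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  t(epoch_loss), val_auc = vm$auc,
                                  val_acc = vm$accuracy)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2g  loss %.4f  val AUC %.3f",
                        epoch, lr, epoch_loss["total"], vm$auc))
      if (is.finite(vm$auc) && vm$auc > best$auc)
        best <- list(auc = vm$auc, params = params, epoch = epoch)
    }
  })

  if (!is.finite(best$auc)) best <- list(auc = NA_real_, params = params,
                                         epoch = train$epochs)
  structure(list(params = best$params, final_params = params,
                 best_epoch = best$epoch, best_val_auc = best$auc,
                 logs = do.call(rbind, logs), mode = mode,
                 attention = attention, loss = loss, train = train,
                 preprocess = preprocess, stats = stats,
                 channel_meta = cohort$channel_meta, T_max = T_max,
                 splits = splits, cohort = cohort,
                 exclusions = exclusions, call = call),
            class = "akinet")
}

# forward-only predictions for a prepared batch
predict_batch <- function(params, batch, mode, attention = TRUE) {
  cfg <- loss_config()
  res <- akinet_loss_grad(params, batch, cfg, mode, attention = attention)
  if (mode == "sequence") {
    list(step = res$fitted,
         patient = patient_scores(res$fitted, batch$pad_mask),
         alpha = NULL)
  } else {
    list(step = NULL, patient = res$fitted, alpha = res$alpha)
  }
}

# per-class accuracy of the current model on its training data
class_accuracies <- function(pred, batch, mode) {
  if (mode == "sequence") {
    y <- batch$labels[batch$pad_mask]
    p <- pred$step[batch$pad_mask]
  } else {
    y <- batch$outcomes[, 1L]
    p <- pred$patient
  }
  yhat <- as.integer(p >= 0.5)
  vapply(0:1, function(cl) {
    if (!any(y == cl)) return(0.5)
    mean(yhat[y == cl] == cl)
  }, 1.0)
}
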