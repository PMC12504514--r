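#' Dynamic evaluation: elastic-anchored online adaptation at inference
#'
#' Processes a stream of patient windows. For each window, predictions are
#' emitted with the current parameters *before* any update; then, when the
#' window carries observed labels, one stochastic gradient step is taken on
#' the window's masked sequence cross-entropy and the parameters are pulled
#' back toward the trained anchor by the exact proximal map of the elastic
#' penalty `(lambda/2) ||theta - theta*||^2`:
#' `theta <- theta* + (theta_sgd - theta*) / (1 + eta * lambda)`.
#' This form has the two limits the anchoring is meant to guarantee:
#' `eta = 0` reproduces static inference exactly, and `lambda = Inf` pins
#' the parameters at the anchor. Windows without labels produce predictions
#' only.
#'
#' @param object A fitted [akinet()] model (sequence mode) whose parameters
#'   serve as the anchor `theta*`.
#' @param stream List of [aki_cohort()] windows, in arrival order.
#' @param eta Online learning rate.
#' @param elastic_lambda Elastic anchoring strength (`Inf` pins to the
#'   anchor).
#' @param use_labels Use each window's labels for the update (default
#'   `TRUE`).
#' @return List with `predictions` (per-window per-patient scores emitted
#'   before each update), `logloss` (per-window mean per-step log-loss of
#'   those predictions), and `params` (the final adapted parameters).
#' @export
dynamic_evaluate <- function(object, stream, eta = 1e-3,
                             elastic_lambda = 1, use_labels = TRUE) {
  stopifnot(object$mode == "sequence")
  anchor <- object$params
  theta <- anchor
  cfg <- loss_config(prob_clip_eps = object$loss$prob_clip_eps)
  preds <- vector("list", length(stream))
  ll <- numeric(length(stream))
  for (w in seq_along(stream)) {
    batch <- prepare_batch(object, stream[[w]])
    res <- akinet_loss_grad(theta, batch, cfg, "sequence")
    preds[[w]] <- patient_scores(res$fitted, batch$pad_mask)
    p <- clip_prob(res$fitted[batch$pad_mask], cfg$prob_clip_eps)
    y <- batch$labels[batch$pad_mask]
    ll[w] <- -mean(y * log(p) + (1 - y) * log(1 - p))
    if (use_labels && eta > 0) {
      if (is.infinite(elastic_lambda)) {
        theta <- anchor
      } else {
        theta_sgd <- params_axpy(theta, res$grads, -eta)
        shrink <- 1 / (1 + eta * elastic_lambda)
        for (nm in names(theta))
          theta[[nm]] <- anchor[[nm]] + (theta_sgd[[nm]] - anchor[[nm]]) * shrink
      }
    }
  }
  list(predictions = preds, logloss = ll, params = theta)
}
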