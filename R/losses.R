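#' Loss configuration
#'
#' Regularisation strengths and data-term options for the composite training
#' objective. The total objective is the masked data term plus the L2 weight
#' penalty, the temporal smoothness penalty, the attention-entropy term
#' (pooled mode), and the multi-task term when task weighting is configured.
#'
#' @param data_loss `"bce"` (masked sequence cross-entropy), `"weighted"`
#'   (instance-weighted by class), or `"focal"`.
#' @param l2_lambda L2 strength on weight matrices (biases and
#'   log-uncertainties excluded).
#' @param smooth_gamma Strength of the squared-difference penalty on
#'   consecutive per-step risks.
#' @param entropy_beta Strength of the attention-entropy regulariser.
#' @param entropy_sign `"diversity"` (default; the term is `-beta * H`, so
#'   minimising it spreads attention, matching the stated intent of the
#'   regulariser) or `"concentration"` (`+beta * H`, the literal penalty on
#'   entropy).
#' @param focal_alpha,focal_gamma Focal-loss scaling and focusing strengths.
#' @param focal_symmetric Include the symmetric negative-class focal term
#'   (default `TRUE`; the positive-only form carries no gradient for
#'   negative instances).
#' @param class_weights Optional per-class weights `c(negative, positive)`
#'   for the weighted data term, e.g. from [inverse_class_weights()].
#' @param dynamic_temp Temperature of the accuracy-driven dynamic weight
#'   update ([dynamic_weight_update()]).
#' @param task_lambdas Fixed per-task weights (length 3) enabling the
#'   multi-task term; `NULL` disables it.
#' @param use_uncertainty Use trainable uncertainty weighting
#'   `sum_k L_k / (2 sigma_k^2) + log sigma_k` instead of fixed lambdas.
#' @param prob_clip_eps Probability clipping bound guarding the logarithms.
#' @return An object of class `"loss_config"`.
#' @export
loss_config <- function(data_loss = c("bce", "weighted", "focal"),
                        l2_lambda = 0, smooth_gamma = 0, entropy_beta = 0,
                        entropy_sign = c("diversity", "concentration"),
                        focal_alpha = 1, focal_gamma = 2,
                        focal_symmetric = TRUE, class_weights = NULL,
                        dynamic_temp = 2, task_lambdas = NULL,
                        use_uncertainty = FALSE, prob_clip_eps = 1e-7) {
  stopifnot(l2_lambda >= 0, smooth_gamma >= 0, entropy_beta >= 0,
            focal_alpha >= 0, focal_gamma >= 0, prob_clip_eps > 0)
  if (!is.null(class_weights) && any(class_weights <= 0))
    stop("class_weights must be strictly positive")
  structure(list(data_loss = match.arg(data_loss), l2_lambda = l2_lambda,
                 smooth_gamma = smooth_gamma, entropy_beta = entropy_beta,
                 entropy_sign = match.arg(entropy_sign),
                 focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 focal_symmetric = isTRUE(focal_symmetric),
                 class_weights = class_weights, dynamic_temp = dynamic_temp,
                 task_lambdas = task_lambdas,
                 use_uncertainty = isTRUE(use_uncertainty),
                 prob_clip_eps = prob_clip_eps),
            class = "loss_config")
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Masked sequence binary cross-entropy
#'
#' Per-patient sum of the two-term cross-entropy over real steps, averaged
#' over patients (so regularisation strengths are batch-size invariant).
#'
#' @param y Labels: vector (one sequence) or `B x T` matrix.
#' @param yhat Predicted probabilities, same shape.
#' @param pad_mask Logical mask of real steps, same shape; default all real.
#' @param eps Probability clipping bound.
#' @return Scalar loss.
#' @export
bce_sequence <- function(y, yhat, pad_mask = NULL, eps = 1e-7) {
  if (!is.matrix(y)) { y <- rbind(y); yhat <- rbind(yhat)
    if (!is.null(pad_mask)) pad_mask <- rbind(pad_mask) }
  if (!identical(dim(y), dim(yhat))) stop("y and yhat shapes differ")
  if (is.null(pad_mask)) pad_mask <- matrix(TRUE, nrow(y), ncol(y))
  p <- clip_prob(yhat, eps)
  ll <- -(y * log(p) + (1 - y) * log(1 - p)) * pad_mask
  mean(rowSums(ll))
}

#' Instance-weighted binary cross-entropy
#'
#' Each instance's two-term cross-entropy is multiplied by its weight
#' `w_i` (the printed cost-sensitive form, where the weight multiplies both
#' terms), then averaged over instances.
#'
#' @param y Binary labels.
#' @param yhat Predicted probabilities.
#' @param weights Positive instance weights `w_i`.
#' @param eps Probability clipping bound.
#' @return Scalar loss.
#' @export
weighted_bce <- function(y, yhat, weights, eps = 1e-7) {
  if (any(weights <= 0)) stop("weights must be strictly positive")
  p <- clip_prob(yhat, eps)
  mean(-weights * (y * log(p) + (1 - y) * log(1 - p)))
}

#' Inverse-class-frequency weights
#'
#' `w_c = N / (2 N_c)`; for two classes the aggregate contribution of each
#' class is balanced: `sum_c N_c w_c = N`.
#'
#' @param counts Named or unnamed vector of per-class counts `N_c`.
#' @return Per-class weights in the same order.
#' @export
inverse_class_weights <- function(counts) {
  if (any(counts <= 0)) stop("every class must be non-empty")
  sum(counts) / (2 * counts)
}

#' Accuracy-driven dynamic class weight
#'
#' `w_c(t+1) = sigmoid(gamma * (0.5 - p_c(t)))`: a class predicted with
#' accuracy 0.5 keeps weight 0.5; harder classes (lower accuracy) gain
#' weight, easier classes lose it.
#'
#' @param p_c Per-class accuracy in `[0, 1]`.
#' @param temp Temperature `gamma` controlling sensitivity.
#' @return Updated weight(s) in (0, 1).
#' @export
dynamic_weight_update <- function(p_c, temp = 2) {
  stopifnot(all(p_c >= 0 & p_c <= 1))
  stats::plogis(temp * (0.5 - p_c))
}

# multiplicative combination of static and dynamic class weights,
# renormalised to mean 1 over the instances of a batch
combine_class_weights <- function(static_w, dynamic_w, y) {
  w <- (static_w * dynamic_w)[y + 1L]
  w / mean(w)
}

#' Focal loss
#'
#' The positive-class term `-alpha (1 - p)^gamma y log p` as printed, plus
#' (by default) the symmetric negative-class term
#' `-alpha p^gamma (1 - y) log(1 - p)`; mean over instances. With
#' `gamma = 0, alpha = 1` and the symmetric term on, reduces to plain
#' cross-entropy.
#'
#' @param y Binary labels.
#' @param yhat Predicted probabilities.
#' @param alpha Class-imbalance scaling.
#' @param gamma Focusing strength (must be non-negative).
#' @param symmetric Include the negative-class term (default `TRUE`).
#' @param eps Probability clipping bound.
#' @return Scalar loss.
#' @export
focal_loss <- function(y, yhat, alpha = 1, gamma = 2, symmetric = TRUE,
                       eps = 1e-7) {
  if (gamma < 0) stop("gamma must be non-negative")
  p <- clip_prob(yhat, eps)
  pos <- -alpha * (1 - p)^gamma * y * log(p)
  neg <- if (symmetric) -alpha * p^gamma * (1 - y) * log(1 - p) else 0
  mean(pos + neg)
}

#' Temporal smoothness penalty
#'
#' `gamma * sum_{t >= 2} (yhat_t - yhat_{t-1})^2` over consecutive real
#' steps of each sequence (batch mean over patients); penalises abrupt
#' changes in the predicted risk trajectory.
#'
#' @param yhat Probabilities: vector or `B x T` matrix.
#' @param pad_mask Logical mask of real steps.
#' @param gamma Penalty strength.
#' @return Scalar penalty (0 for sequences with fewer than 2 real steps).
#' @export
smoothness_penalty <- function(yhat, pad_mask = NULL, gamma = 1) {
  if (!is.matrix(yhat)) { yhat <- rbind(yhat)
    if (!is.null(pad_mask)) pad_mask <- rbind(pad_mask) }
  if (is.null(pad_mask)) pad_mask <- matrix(TRUE, nrow(yhat), ncol(yhat))
  T_len <- ncol(yhat)
  if (T_len < 2L) return(0)
  d <- yhat[, 2:T_len, drop = FALSE] - yhat[, 1:(T_len - 1), drop = FALSE]
  both <- pad_mask[, 2:T_len, drop = FALSE] & pad_mask[, 1:(T_len - 1), drop = FALSE]
  gamma * mean(rowSums(d^2 * both))
}

#' Attention-entropy regularisation term
#'
#' For attention weights on the simplex, the Shannon entropy
#' `H = -sum_t alpha_t log alpha_t` enters the objective as `-beta * H`
#' under `sign = "diversity"` (minimising the total then spreads attention
#' and prevents collapse onto a single step) or `+beta * H` under
#' `sign = "concentration"` (the literal entropy penalty). `0 log 0` is
#' taken as 0.
#'
#' @param alpha Attention weights (vector on the simplex, or `B x T` matrix
#'   of rows on the simplex; batch mean is returned).
#' @param beta Regularisation strength.
#' @param sign `"diversity"` or `"concentration"`.
#' @return Scalar additive loss term.
#' @export
attention_entropy_term <- function(alpha, beta = 1,
                                   sign = c("diversity", "concentration")) {
  sign <- match.arg(sign)
  if (!is.matrix(alpha)) alpha <- rbind(alpha)
  H <- apply(alpha, 1, function(a) {
    a <- a[a > 0]
    -sum(a * log(a))
  })
  s <- if (sign == "diversity") -1 else 1
  s * beta * mean(H)
}

#' Squared L2 norm of the weight matrices
#'
#' @param params An [akinet_params()] object.
#' @return `sum of squared entries` over weight matrices (biases and
#'   log-uncertainties excluded).
#' @export
l2_penalty <- function(params) {
  sum(vapply(l2_param_names(), function(nm) sum(params[[nm]]^2), 1.0))
}

#' Multi-task loss combination
#'
#' Fixed mode: `sum_k lambda_k L_k`. Uncertainty mode:
#' `sum_k L_k / (2 sigma_k^2) + log sigma_k` with `sigma_k = exp(log_sigma_k)`
#' trainable.
#'
#' @param task_losses Vector of per-task losses `L_k`.
#' @param config A [loss_config()]; `task_lambdas` and `use_uncertainty`
#'   select the mode.
#' @param log_sigma Per-task log-uncertainties (uncertainty mode).
#' @return Scalar combined loss.
#' @export
multitask_loss <- function(task_losses, config = loss_config(),
                           log_sigma = NULL) {
  if (config$use_uncertainty) {
    if (is.null(log_sigma)) log_sigma <- numeric(length(task_losses))
    sum(task_losses * exp(-2 * log_sigma) / 2 + log_sigma)
  } else {
    lam <- config$task_lambdas %||% rep(1, length(task_losses))
    sum(lam * task_losses)
  }
}

#' Assemble the composite objective from its parts
#'
#' Records every term and their configured combination; the identity
#' `total = data + l2 + smooth + entropy + multitask` holds exactly.
#'
#' @param data_term Data-fit loss value.
#' @param config A [loss_config()].
#' @param params Optional parameters (for the L2 term; 0 if omitted).
#' @param smooth_term,entropy_term Precomputed penalty values (already
#'   scaled by their strengths).
#' @param task_losses Optional per-task losses for the multi-task term.
#' @param log_sigma Per-task log-uncertainties (uncertainty mode).
#' @return A list of class `"loss_breakdown"` with fields `data_term`,
#'   `l2_term`, `smooth_term`, `entropy_term`, `task_terms`,
#'   `multitask_term`, `total`.
#' @export
total_loss <- function(data_term, config = loss_config(), params = NULL,
                       smooth_term = 0, entropy_term = 0,
                       task_losses = NULL, log_sigma = NULL) {
  l2_term <- if (is.null(params)) 0 else config$l2_lambda * l2_penalty(params)
  mt <- if (is.null(task_losses)) 0 else
    multitask_loss(task_losses, config, log_sigma)
  structure(list(data_term = data_term, l2_term = l2_term,
                 smooth_term = smooth_term, entropy_term = entropy_term,
                 task_terms = task_losses, multitask_term = mt,
                 total = data_term + l2_term + smooth_term + entropy_term + mt),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total %.6g = data %.6g + l2 %.6g + smooth %.6g + entropy %.6g + multitask %.6g\n",
              x$total, x$data_term, x$l2_term, x$smooth_term,
              x$entropy_term, x$multitask_term))
  invisible(x)
}
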