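# Analytic gradients of the composite objective.
#
# One batched forward/backward pass through the LSTM encoder, the per-step or
# attention-pooled risk head, the multi-task heads, and all penalties. The
# returned gradient list has exactly the shapes of the parameter list; every
# entry is checked against central finite differences in the test suite.

# elementwise data-term value and logit-derivative for one variant.
# `w` are optional elementwise weights (already aligned with y/p).
data_term_parts <- function(y, p, config, w = NULL) {
  eps <- config$prob_clip_eps
  p <- clip_prob(p, eps)
  if (config$data_loss == "focal") {
    a <- config$focal_alpha; g <- config$focal_gamma
    L <- -a * (1 - p)^g * y * log(p)
    dz <- y * (a * g * p * (1 - p)^g * log(p) - a * (1 - p)^(g + 1))
    if (config$focal_symmetric) {
      L <- L - a * p^g * (1 - y) * log(1 - p)
      dz <- dz + (1 - y) * (-a * g * p^g * (1 - p) * log(1 - p) + a * p^(g + 1))
    }
    if (!is.null(w)) {            # class-balanced focal: w_c modulates both terms
      L <- w * L
      dz <- w * dz
    }
  } else {
    L <- -(y * log(p) + (1 - y) * log(1 - p))
    dz <- p - y
    if (config$data_loss == "weighted") {
      if (is.null(w)) w <- 1
      L <- w * L
      dz <- w * dz
    }
  }
  list(L = L, dz = dz)
}

# elementwise class weights from config, renormalised to mean 1 over the
# selected (real) elements; NULL unless the weighted data term is active
elementwise_weights <- function(labels, mask, config) {
  if (config$data_loss == "bce" || is.null(config$class_weights)) return(NULL)
  cw <- config$class_weights
  w <- matrix(cw[labels + 1L], nrow(labels), ncol(labels))
  w / mean(w[mask])
}

# multi-task head forward/backward on a shared representation S (B x d_h)
multitask_parts <- function(S, outcomes, params, config) {
  B <- nrow(S)
  K <- nrow(params$A_task)
  Z <- sweep(S %*% t(params$A_task), 2, params$b_task, "+")
  P <- clip_prob(stats::plogis(Z), config$prob_clip_eps)
  Y <- outcomes[, seq_len(K), drop = FALSE]
  task_losses <- colMeans(-(Y * log(P) + (1 - Y) * log(1 - P)))
  coefs <- if (config$use_uncertainty) 0.5 * exp(-2 * params$log_sigma)
           else (config$task_lambdas %||% rep(1, K))
  dZ <- sweep(P - Y, 2, coefs, "*") / B
  dlog_sigma <- if (config$use_uncertainty)
    1 - task_losses * exp(-2 * params$log_sigma) else numeric(K)
  value <- multitask_loss(task_losses, config, params$log_sigma)
  list(value = value, task_losses = task_losses,
       dA = crossprod(dZ, S), db = colSums(dZ), dS = dZ %*% params$A_task,
       dlog_sigma = dlog_sigma, P = P)
}

# backpropagation through time given external per-step gradients dH_ext
bptt <- function(params, batch, cache, dH_ext, grads) {
  inputs <- batch$inputs; M <- batch$pad_mask
  B <- dim(inputs)[1]; T_len <- dim(inputs)[2]
  d_h <- length(params$b_i)
  dh_carry <- matrix(0, B, d_h)
  dc_carry <- matrix(0, B, d_h)
  zero <- matrix(0, B, d_h)
  for (t in rev(seq_len(T_len))) {
    m <- M[, t]
    dh_tot <- dH_ext[[t]] + dh_carry
    dc_tot <- dc_carry
    dh_raw <- dh_tot * m
    dh_prev <- dh_tot * (1 - m)
    dc_raw <- dc_tot * m
    dc_prev_pass <- dc_tot * (1 - m)
    I <- cache$I[[t]]; F_ <- cache$F_[[t]]; O <- cache$O[[t]]
    G <- cache$G[[t]]; Tc <- cache$Tc[[t]]
    do_ <- dh_raw * Tc
    dc_raw <- dc_raw + dh_raw * O * (1 - Tc^2)
    C_prev <- if (t > 1) cache$C[[t - 1]] else zero
    H_prev <- if (t > 1) cache$H[[t - 1]] else zero
    df <- dc_raw * C_prev
    di <- dc_raw * G
    dg <- dc_raw * I
    dc_prev <- dc_raw * F_
    da_i <- di * I * (1 - I)
    da_f <- df * F_ * (1 - F_)
    da_o <- do_ * O * (1 - O)
    da_g <- dg * (1 - G^2)
    X_t <- inputs[, t, , drop = TRUE]
    if (is.null(dim(X_t))) X_t <- matrix(X_t, nrow = B)
    grads$W_i <- grads$W_i + crossprod(da_i, X_t)
    grads$U_i <- grads$U_i + crossprod(da_i, H_prev)
    grads$b_i <- grads$b_i + colSums(da_i)
    grads$W_f <- grads$W_f + crossprod(da_f, X_t)
    grads$U_f <- grads$U_f + crossprod(da_f, H_prev)
    grads$b_f <- grads$b_f + colSums(da_f)
    grads$W_o <- grads$W_o + crossprod(da_o, X_t)
    grads$U_o <- grads$U_o + crossprod(da_o, H_prev)
    grads$b_o <- grads$b_o + colSums(da_o)
    grads$W_c <- grads$W_c + crossprod(da_g, X_t)
    grads$U_c <- grads$U_c + crossprod(da_g, H_prev)
    grads$b_c <- grads$b_c + colSums(da_g)
    dh_carry <- dh_prev + da_i %*% params$U_i + da_f %*% params$U_f +
      da_o %*% params$U_o + da_g %*% params$U_c
    dc_carry <- dc_prev_pass + dc_prev
  }
  grads
}

#' Composite loss and analytic gradients for one batch
#'
#' Runs the full forward pass in the requested prediction mode and
#' backpropagates the composite objective through every parameter.
#' In `"sequence"` mode the data term is the masked per-step loss on the
#' AKI label sequence plus the temporal smoothness penalty; in `"pooled"`
#' mode it is the patient-level loss on the attention-pooled risk plus the
#' attention-entropy term. The L2 penalty and (when configured) the
#' multi-task term are added in both modes.
#'
#' @param params An [akinet_params()] object.
#' @param batch A [pad_and_mask()] batch; fields `static` (`B x p` matrix)
#'   and `outcomes` (`B x 3`) are used when present (see [build_batch()]).
#' @param config A [loss_config()].
#' @param mode `"sequence"` or `"pooled"`.
#' @param attention In pooled mode, `FALSE` replaces the attention pool by
#'   the final real hidden state (the no-attention ablation).
#' @return List with `breakdown` (a `loss_breakdown`), `grads` (parameter
#'   shaped gradient list), `fitted` (per-step `B x T` probabilities in
#'   sequence mode; patient-level vector in pooled mode), and `alpha`
#'   (`B x T` attention weights, pooled mode with attention only).
#' @export
akinet_loss_grad <- function(params, batch, config = loss_config(),
                             mode = c("sequence", "pooled"),
                             attention = TRUE) {
  mode <- match.arg(mode)
  inputs <- batch$inputs; M <- batch$pad_mask
  B <- dim(inputs)[1]; T_len <- dim(inputs)[2]
  d_h <- length(params$b_i)
  cache <- lstm_forward(params, batch)
  grads <- params_zero(params)
  dH_ext <- rep(list(matrix(0, B, d_h)), T_len)
  use_mt <- config$use_uncertainty || !is.null(config$task_lambdas)
  if (use_mt && is.null(batch$outcomes))
    stop("multi-task loss configured but the batch has no outcomes")
  smooth_term <- 0; entropy_term <- 0
  task_losses <- NULL; mt <- NULL
  alpha_out <- NULL

  if (mode == "sequence") {
    Y <- batch$labels
    Z <- matrix(0, B, T_len)
    for (t in seq_len(T_len))
      Z[, t] <- cache$H[[t]] %*% params$w_out + params$b_out
    P <- stats::plogis(Z)
    W_el <- elementwise_weights(Y, M, config)
    parts <- data_term_parts(Y, P, config, W_el)
    data_term <- mean(rowSums(parts$L * M))
    dZ <- parts$dz * M / B
    if (config$smooth_gamma > 0 && T_len > 1) {
      D <- (P[, 2:T_len, drop = FALSE] - P[, 1:(T_len - 1), drop = FALSE])
      both <- M[, 2:T_len, drop = FALSE] & M[, 1:(T_len - 1), drop = FALSE]
      smooth_term <- config$smooth_gamma * mean(rowSums(D^2 * both))
      dP <- matrix(0, B, T_len)
      dP[, 2:T_len] <- dP[, 2:T_len] + 2 * config$smooth_gamma * D * both / B
      dP[, 1:(T_len - 1)] <- dP[, 1:(T_len - 1)] - 2 * config$smooth_gamma * D * both / B
      dZ <- dZ + dP * P * (1 - P)
    }
    for (t in seq_len(T_len)) {
      grads$w_out <- grads$w_out + drop(crossprod(cache$H[[t]], dZ[, t]))
      grads$b_out <- grads$b_out + sum(dZ[, t])
      dH_ext[[t]] <- dH_ext[[t]] + outer(dZ[, t], params$w_out)
    }
    if (use_mt) {
      S <- t(vapply(seq_len(B), function(b) cache$H[[batch$lengths[b]]][b, ],
                    numeric(d_h)))
      mtp <- multitask_parts(S, batch$outcomes, params, config)
      task_losses <- mtp$task_losses; mt <- mtp$value
      grads$A_task <- grads$A_task + mtp$dA
      grads$b_task <- grads$b_task + mtp$db
      grads$log_sigma <- grads$log_sigma + mtp$dlog_sigma
      for (b in seq_len(B)) {
        tb <- batch$lengths[b]
        dH_ext[[tb]][b, ] <- dH_ext[[tb]][b, ] + mtp$dS[b, ]
      }
    }
    fitted <- P
  } else {
    # ---- pooled mode ----
    y <- batch$outcomes[, 1L]
    if (attention) {
      adaptive <- ncol(params$W_z) > 0 && !is.null(batch$static)
      V <- if (adaptive)
        sweep(batch$static %*% t(params$W_z), 2, params$b_z, "+")
      else matrix(params$v, B, length(params$v), byrow = TRUE)
      U_list <- vector("list", T_len)
      S_mat <- matrix(-Inf, B, T_len)
      for (t in seq_len(T_len)) {
        U_t <- tanh(sweep(cache$H[[t]] %*% t(params$W_h), 2, params$b_h, "+"))
        U_list[[t]] <- U_t
        S_mat[, t] <- rowSums(U_t * V)
      }
      S_mat[!M] <- -Inf
      if (any(rowSums(M) == 0)) stop("attention is undefined for an all-padded row")
      S_shift <- S_mat - apply(S_mat, 1, max)
      E <- exp(S_shift); E[!M] <- 0
      alpha <- E / rowSums(E)
      Cvec <- matrix(0, B, d_h)
      for (t in seq_len(T_len)) Cvec <- Cvec + alpha[, t] * cache$H[[t]]
      alpha_out <- alpha
    } else {
      Cvec <- t(vapply(seq_len(B), function(b) cache$H[[batch$lengths[b]]][b, ],
                       numeric(d_h)))
      alpha <- NULL
    }
    z <- drop(Cvec %*% params$w_pool) + params$b_pool
    p <- stats::plogis(z)
    W_el <- if (config$data_loss != "bce" && !is.null(config$class_weights)) {
      w <- config$class_weights[y + 1L]; w / mean(w)
    } else NULL
    parts <- data_term_parts(y, p, config, W_el)
    data_term <- mean(parts$L)
    dz <- parts$dz / B
    grads$w_pool <- grads$w_pool + drop(crossprod(Cvec, dz))
    grads$b_pool <- grads$b_pool + sum(dz)
    dC <- outer(dz, params$w_pool)
    if (use_mt) {
      mtp <- multitask_parts(Cvec, batch$outcomes, params, config)
      task_losses <- mtp$task_losses; mt <- mtp$value
      grads$A_task <- grads$A_task + mtp$dA
      grads$b_task <- grads$b_task + mtp$db
      grads$log_sigma <- grads$log_sigma + mtp$dlog_sigma
      dC <- dC + mtp$dS
    }
    if (attention) {
      dAlpha <- matrix(0, B, T_len)
      for (t in seq_len(T_len)) {
        dAlpha[, t] <- rowSums(dC * cache$H[[t]])
        dH_ext[[t]] <- dH_ext[[t]] + alpha[, t] * dC
      }
      if (config$entropy_beta > 0) {
        sgn <- if (config$entropy_sign == "diversity") -1 else 1
        H_ent <- rowSums(ifelse(alpha > 0, -alpha * log(alpha), 0))
        entropy_term <- sgn * config$entropy_beta * mean(H_ent)
        dAlpha_ent <- matrix(0, B, T_len)
        pos <- alpha > 0
        dAlpha_ent[pos] <- sgn * config$entropy_beta * (-(log(alpha[pos]) + 1)) / B
        dAlpha <- dAlpha + dAlpha_ent
      }
      inner <- rowSums(alpha * dAlpha)
      dS_mat <- alpha * (dAlpha - inner)
      dV <- matrix(0, B, ncol(V))
      for (t in seq_len(T_len)) {
        dU_t <- dS_mat[, t] * V
        dA_t <- dU_t * (1 - U_list[[t]]^2)
        grads$W_h <- grads$W_h + crossprod(dA_t, cache$H[[t]])
        grads$b_h <- grads$b_h + colSums(dA_t)
        dH_ext[[t]] <- dH_ext[[t]] + dA_t %*% params$W_h
        dV <- dV + dS_mat[, t] * U_list[[t]]
      }
      if (adaptive) {
        grads$W_z <- grads$W_z + crossprod(dV, batch$static)
        grads$b_z <- grads$b_z + colSums(dV)
      } else {
        grads$v <- grads$v + colSums(dV)
      }
    } else {
      for (b in seq_len(B)) {
        tb <- batch$lengths[b]
        dH_ext[[tb]][b, ] <- dH_ext[[tb]][b, ] + dC[b, ]
      }
    }
    fitted <- p
  }

  grads <- bptt(params, batch, cache, dH_ext, grads)
  if (config$l2_lambda > 0)
    for (nm in l2_param_names())
      grads[[nm]] <- grads[[nm]] + 2 * config$l2_lambda * params[[nm]]
  breakdown <- total_loss(data_term, config, params = params,
                          smooth_term = smooth_term,
                          entropy_term = entropy_term,
                          task_losses = task_losses,
                          log_sigma = params$log_sigma)
  list(breakdown = breakdown, grads = grads, fitted = fitted,
       alpha = alpha_out)
}
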