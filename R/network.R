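#' Single LSTM cell update
#'
#' The gated recurrence: input gate `i = sigmoid(W_i x + U_i h + b_i)`,
#' forget gate `f = sigmoid(W_f x + U_f h + b_f)`, candidate memory
#' `g = tanh(W_c x + U_c h + b_c)`, cell `c' = f * c + i * g`, output gate
#' `o = sigmoid(W_o x + U_o h + b_o)`, hidden `h' = o * tanh(c')`.
#'
#' @param x Input vector of length `d`.
#' @param state List with hidden vector `h` and cell vector `c` (length
#'   `d_h`); defaults to zeros.
#' @param params An [akinet_params()] object.
#' @return List with updated `h` and `c` and the gate activations
#'   (`i`, `f`, `o`, `g`).
#' @export
lstm_step <- function(x, state = NULL, params) {
  d_h <- length(params$b_i)
  if (is.null(state)) state <- list(h = numeric(d_h), c = numeric(d_h))
  if (any(!is.finite(x)))
    stop("non-finite input to lstm_step")
  i <- stats::plogis(drop(params$W_i %*% x + params$U_i %*% state$h) + params$b_i)
  f <- stats::plogis(drop(params$W_f %*% x + params$U_f %*% state$h) + params$b_f)
  g <- tanh(drop(params$W_c %*% x + params$U_c %*% state$h) + params$b_c)
  o <- stats::plogis(drop(params$W_o %*% x + params$U_o %*% state$h) + params$b_o)
  c_new <- f * state$c + i * g
  list(h = o * tanh(c_new), c = c_new, i = i, f = f, o = o, g = g)
}

# batched forward pass over a padded batch; returns hidden states and the
# per-step cache needed for backpropagation. On padded steps the previous
# state is carried forward unchanged, so prepending masked padding never
# alters real-step outputs.
lstm_forward <- function(params, batch) {
  inputs <- batch$inputs
  M <- batch$pad_mask
  B <- dim(inputs)[1]; T_len <- dim(inputs)[2]
  d_h <- length(params$b_i)
  H_prev <- matrix(0, B, d_h); C_prev <- matrix(0, B, d_h)
  cache <- list(I = vector("list", T_len), F_ = vector("list", T_len),
                O = vector("list", T_len), G = vector("list", T_len),
                Craw = vector("list", T_len), Tc = vector("list", T_len),
                H = vector("list", T_len), C = vector("list", T_len))
  for (t in seq_len(T_len)) {
    X_t <- inputs[, t, , drop = TRUE]
    if (is.null(dim(X_t))) X_t <- matrix(X_t, nrow = B)
    I <- stats::plogis(sweep(X_t %*% t(params$W_i) + H_prev %*% t(params$U_i), 2, params$b_i, "+"))
    F_ <- stats::plogis(sweep(X_t %*% t(params$W_f) + H_prev %*% t(params$U_f), 2, params$b_f, "+"))
    G <- tanh(sweep(X_t %*% t(params$W_c) + H_prev %*% t(params$U_c), 2, params$b_c, "+"))
    O <- stats::plogis(sweep(X_t %*% t(params$W_o) + H_prev %*% t(params$U_o), 2, params$b_o, "+"))
    Craw <- F_ * C_prev + I * G
    Tc <- tanh(Craw)
    Hraw <- O * Tc
    m <- M[, t]
    C_t <- Craw * m + C_prev * (1 - m)
    H_t <- Hraw * m + H_prev * (1 - m)
    cache$I[[t]] <- I; cache$F_[[t]] <- F_; cache$O[[t]] <- O
    cache$G[[t]] <- G; cache$Craw[[t]] <- Craw; cache$Tc[[t]] <- Tc
    cache$H[[t]] <- H_t; cache$C[[t]] <- C_t
    H_prev <- H_t; C_prev <- C_t
  }
  cache
}

#' Encode a padded batch into per-step hidden states
#'
#' @param batch A [pad_and_mask()] batch.
#' @param params An [akinet_params()] object.
#' @return Array `B x T_max x d_h` of hidden states; padded steps carry the
#'   last real state forward (they are excluded from all heads and losses
#'   via the pad mask).
#' @export
encode_sequence <- function(batch, params) {
  cache <- lstm_forward(params, batch)
  B <- dim(batch$inputs)[1]; T_len <- dim(batch$inputs)[2]
  d_h <- length(params$b_i)
  H <- array(0, c(B, T_len, d_h))
  for (t in seq_len(T_len)) H[, t, ] <- cache$H[[t]]
  H
}

#' Per-step AKI risk from a hidden state
#'
#' `sigmoid(w_out . h + b_out)`, the fully connected layer with sigmoid
#' activation applied to each hidden state.
#'
#' @param h Hidden vector (length `d_h`) or matrix (`B x d_h`).
#' @param params An [akinet_params()] object.
#' @return Probability (or vector of probabilities) in (0, 1).
#' @export
step_risk <- function(h, params) {
  if (is.matrix(h)) drop(stats::plogis(h %*% params$w_out + params$b_out))
  else stats::plogis(sum(params$w_out * h) + params$b_out)
}

#' Temporal attention weights over a hidden-state sequence
#'
#' Scores `e_t = v' tanh(W_h h_t + b_h)` (with the query `v` replaced by the
#' patient-adaptive `W_z z + b_z` when a context vector `z` is supplied),
#' softmax-normalised over real steps. Padded steps receive zero weight.
#'
#' @param H Matrix `T x d_h` of hidden states for one patient.
#' @param params An [akinet_params()] object.
#' @param z Optional static-context vector for the adaptive query.
#' @param mask Optional logical vector of real steps (default all real).
#' @return Attention weights on the probability simplex over real steps.
#' @export
attention_weights <- function(H, params, z = NULL, mask = NULL) {
  T_len <- nrow(H)
  if (is.null(mask)) mask <- rep(TRUE, T_len)
  if (!any(mask)) stop("attention is undefined when every step is padded")
  v <- if (is.null(z)) params$v else drop(params$W_z %*% z) + params$b_z
  U <- tanh(sweep(H %*% t(params$W_h), 2, params$b_h, "+"))
  e <- drop(U %*% v)
  e[!mask] <- -Inf
  e <- e - max(e[mask])
  a <- exp(e)
  a[!mask] <- 0
  a / sum(a)
}

#' Attention-pooled context vector
#'
#' The convex combination `c = sum_t alpha_t h_t`; lies in the convex hull
#' of the hidden states.
#'
#' @param H Matrix `T x d_h`.
#' @param alpha Attention weights from [attention_weights()].
#' @return Context vector of length `d_h`.
#' @export
context_vector <- function(H, alpha) drop(crossprod(H, alpha))

#' Pooled sequence-level risk
#'
#' The pooled head applied to the attention context:
#' `sigmoid(w_pool . c + b_pool)`.
#'
#' @param c_vec Context vector from [context_vector()].
#' @param params An [akinet_params()] object.
#' @return Probability in (0, 1).
#' @export
pooled_risk <- function(c_vec, params) {
  stats::plogis(sum(params$w_pool * c_vec) + params$b_pool)
}

#' Multi-task outcome heads
#'
#' Independent affine-plus-sigmoid heads for the three patient-level
#' outcomes (AKI onset, renal recovery, dialysis requirement) on top of the
#' shared representation (the attention context in pooled mode, the final
#' real hidden state in sequence mode).
#'
#' @param shared Shared representation: vector (length `d_h`) or matrix
#'   (`B x d_h`).
#' @param params An [akinet_params()] object.
#' @return Vector of `K` probabilities (or `B x K` matrix).
#' @export
multitask_forward <- function(shared, params) {
  if (!is.matrix(shared)) shared <- matrix(shared, nrow = 1)
  P <- stats::plogis(sweep(shared %*% t(params$A_task), 2, params$b_task, "+"))
  colnames(P) <- c("aki", "recovery", "dialysis")[seq_len(ncol(P))]
  if (nrow(P) == 1L) drop(P) else P
}
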