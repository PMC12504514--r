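#' Initialise model parameters
#'
#' All trainable tensors of the network: the four LSTM gates (input weights
#' `W_*` of size `d_h x d`, recurrent weights `U_*` of size `d_h x d_h`,
#' biases `b_*`), the attention scorer (`W_h`, `b_h`, context query `v`, and
#' the context-adaptive map `W_z`, `b_z` producing a patient-specific query
#' from static features), the per-step and pooled risk heads, the three task
#' heads, and the per-task log-uncertainties. Weights are drawn uniformly on
#' `(-1/sqrt(fan_in), 1/sqrt(fan_in))`; biases start at zero except the
#' forget-gate biases, which are initialised to a mixture of memory
#' horizons: half of the units get `b_f = log(u)` with `u` uniform on 1-4
#' steps (fast, acute dynamics) and half with `u` uniform on 8-48 steps
#' (slow trends), so the cell states span retention times from an hour to
#' the full observation window from the start of training (the
#' chrono-initialisation idea: `sigmoid(log u) = u / (1 + u)` retains
#' information for about `u` steps).
#'
#' @param d Input feature dimension.
#' @param d_h Hidden width (default 64).
#' @param d_a Attention width (default 32).
#' @param p_static Static-context dimension for the adaptive query (0
#'   disables the adaptive branch).
#' @param n_tasks Number of outcome heads (3: AKI, recovery, dialysis).
#' @param seed RNG seed for the draw.
#' @return An object of class `"akinet_params"`: a named list of arrays.
#' @export
akinet_params <- function(d, d_h = 64L, d_a = 32L, p_static = 0L,
                          n_tasks = 3L, seed = 1L) {
  set.seed(seed)
  u <- function(nr, nc) {
    lim <- 1 / sqrt(nc)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  horizons <- ifelse(seq_len(d_h) %% 2 == 0,
                     stats::runif(d_h, 8, 48), stats::runif(d_h, 1, 4))
  p <- list(
    W_i = u(d_h, d), U_i = u(d_h, d_h), b_i = numeric(d_h),
    W_f = u(d_h, d), U_f = u(d_h, d_h), b_f = log(horizons),
    W_c = u(d_h, d), U_c = u(d_h, d_h), b_c = numeric(d_h),
    W_o = u(d_h, d), U_o = u(d_h, d_h), b_o = numeric(d_h),
    W_h = u(d_a, d_h), b_h = numeric(d_a), v = drop(u(1, d_a)),
    W_z = if (p_static > 0) u(d_a, p_static) else matrix(0, d_a, 0),
    b_z = numeric(d_a),
    # output heads start at zero: the first gradient step then fixes their
    # sign, instead of a random projection of the encoder features deciding
    # whether early predictions are right- or wrong-way-round
    w_out = numeric(d_h), b_out = 0,
    w_pool = numeric(d_h), b_pool = 0,
    A_task = matrix(0, n_tasks, d_h), b_task = numeric(n_tasks),
    log_sigma = numeric(n_tasks))
  structure(p, class = "akinet_params",
            dims = list(d = d, d_h = d_h, d_a = d_a, p_static = p_static,
                        n_tasks = n_tasks))
}

# names of arrays counted as weight matrices for the L2 penalty
# (biases and log-uncertainties are excluded)
l2_param_names <- function() {
  c("W_i", "U_i", "W_f", "U_f", "W_c", "U_c", "W_o", "U_o",
    "W_h", "v", "W_z", "w_out", "w_pool", "A_task")
}

#' Flatten parameters to a named numeric vector (and back)
#'
#' @param params An [akinet_params()] object.
#' @return `flatten_params()`: a named numeric vector;
#'   `unflatten_params()`: the parameter list rebuilt from such a vector.
#' @export
flatten_params <- function(params) {
  out <- unlist(lapply(params, as.numeric))
  names(out) <- unlist(lapply(names(params), function(nm)
    paste0(nm, "[", seq_along(params[[nm]]), "]")))
  out
}

#' @rdname flatten_params
#' @param theta Numeric vector from [flatten_params()].
#' @param template Parameter object providing shapes.
#' @export
unflatten_params <- function(theta, template) {
  pos <- 0L
  out <- template
  for (nm in names(template)) {
    k <- length(template[[nm]])
    vals <- theta[pos + seq_len(k)]
    out[[nm]] <- if (is.matrix(template[[nm]]))
      matrix(vals, nrow(template[[nm]]), ncol(template[[nm]])) else as.numeric(vals)
    pos <- pos + k
  }
  out
}

# elementwise combine two parameter lists: a + s * b (a's shapes/attributes win)
params_axpy <- function(a, b, s = 1) {
  for (nm in names(a)) a[[nm]][] <- a[[nm]] + s * b[[nm]]
  a
}

params_zero <- function(template) {
  for (nm in names(template)) template[[nm]][] <- 0
  template
}

#' Save / load a model checkpoint
#'
#' A checkpoint is the parameter container plus a hash of the configuration
#' that produced it; the round trip is bit-exact.
#'
#' @param params An [akinet_params()] object.
#' @param path File path.
#' @param config Optional configuration list stored alongside (hashed).
#' @return `save_checkpoint()`: `path` invisibly; `load_checkpoint()`: a
#'   list with `params` and `config_hash`.
#' @export
save_checkpoint <- function(params, path, config = NULL) {
  hash <- if (is.null(config)) NA_character_ else
    paste(format(utils::object.size(config)),
          digest_config(config), sep = ":")
  saveRDS(list(params = params, config_hash = hash), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# cheap deterministic config fingerprint (sum of serialized bytes)
digest_config <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% .Machine$integer.max)
}
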