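# shared fixtures built in code

# a hand-sized series with creatinine and urine channels
make_series <- function(creat, urine = NULL, weight = 70, id = "p1",
                        labels = NULL) {
  T_len <- length(creat)
  ch <- list(creatinine = creat)
  if (!is.null(urine)) ch$urine <- urine
  clinical_series(id, ch, weight_kg = weight, labels_aki = labels)
}

# independent brute-force KDIGO oracle: direct enumeration of every
# (step, window) pair, no shared code with label_aki_kdigo
oracle_kdigo <- function(series, thr = kdigo_thresholds()) {
  T_len <- length(series$times)
  scr <- series$channels$creatinine
  scr_obs <- series$observed_mask[, "creatinine"] & !is.na(scr)
  has_u <- !is.null(series$channels$urine)
  y <- integer(T_len)
  for (t in seq_len(T_len)) {
    fired <- FALSE
    if (scr_obs[t]) {
      # absolute rise: any observed step in (t - 48, t]
      for (s in seq_len(t)) {
        if (scr_obs[s] && series$times[s] > series$times[t] - thr$delta_window &&
            scr[t] - scr[s] >= thr$delta_scr) fired <- TRUE
      }
      # relative rise vs 7-day rolling min (earliest-observed fallback)
      win <- which(scr_obs & series$times > series$times[t] - thr$ratio_window &
                     series$times <= series$times[t])
      base <- if (length(win)) min(scr[win]) else scr[which(scr_obs)[1]]
      if (any(scr_obs) && scr[t] >= thr$ratio_scr * base) fired <- TRUE
    }
    if (!fired && has_u && is.finite(series$weight_kg) && series$weight_kg > 0) {
      u_obs <- series$observed_mask[, "urine"] & !is.na(series$channels$urine)
      rate <- series$channels$urine / series$weight_kg
      # longest run of low observed rate ending at t
      run <- 0
      for (s in seq_len(t)) {
        run <- if (u_obs[s] && rate[s] < thr$urine_rate) run + 1 else 0
      }
      if (run > thr$urine_duration) fired <- TRUE
    }
    y[t] <- as.integer(fired)
  }
  y
}

# random series generator for property tests
random_series <- function(T_len, seed, missing = 0.15) {
  set.seed(seed)
  ch <- list(creatinine = round(runif(T_len, 0.6, 2.2), 2),
             urine = round(runif(T_len, 10, 120), 1))
  s <- clinical_series(sprintf("r%d", seed), ch, weight_kg = 70)
  mask <- matrix(runif(T_len * 2) >= missing, T_len,
                 dimnames = list(NULL, c("creatinine", "urine")))
  s$observed_mask <- mask
  for (chn in names(s$channels)) s$channels[[chn]][!mask[, chn]] <- NA_real_
  s
}

# small random model + batch for gradient checks
random_instance <- function(seed, B = 3, T_len = 5, d = 3, d_h = 4, d_a = 3) {
  set.seed(seed)
  params <- akinet_params(d, d_h = d_h, d_a = d_a, p_static = 2, seed = seed)
  for (nm in names(params)) params[[nm]][] <- rnorm(length(params[[nm]]), 0, 0.4)
  pm <- matrix(TRUE, B, T_len)
  if (B > 1) pm[2, (T_len - 1):T_len] <- FALSE
  batch <- structure(list(
    inputs = array(rnorm(B * T_len * d), c(B, T_len, d)),
    pad_mask = pm,
    labels = matrix(rbinom(B * T_len, 1, 0.4), B, T_len),
    lengths = apply(pm, 1, sum),
    static = matrix(rnorm(B * 2), B, 2),
    outcomes = matrix(rbinom(B * 3, 1, 0.5), B, 3)), class = "padded_batch")
  list(params = params, batch = batch)
}

# central finite differences of the total loss
fd_grad <- function(params, batch, cfg, mode, attention = TRUE, h = 1e-5) {
  th <- flatten_params(params)
  loss_at <- function(v) {
    akinet_loss_grad(unflatten_params(v, params), batch, cfg, mode,
                     attention = attention)$breakdown$total
  }
  vapply(seq_along(th), function(k) {
    tp <- th; tp[k] <- th[k] + h
    tm <- th; tm[k] <- th[k] - h
    (loss_at(tp) - loss_at(tm)) / (2 * h)
  }, 1.0)
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1e-6))
}
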