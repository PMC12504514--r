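test_that("short gaps are carry-filled, long gaps fall back to the median", {
  s <- make_series(c(1.0, NA, 1.2), rep(60, 3))
  out <- impute_series(s)
  expect_equal(out$channels$creatinine, c(1.0, 1.0, 1.2))

  # leading run is filled backward from the first observation
  s2 <- make_series(c(NA, NA, 1.1, 1.3))
  expect_equal(impute_series(s2)$channels$creatinine, c(1.1, 1.1, 1.1, 1.3))

  # a run longer than the cap gets the patient median of observed values
  v <- c(2.0, rep(NA, 5), 1.0, 3.0)
  out3 <- impute_series(make_series(v))
  expect_equal(out3$channels$creatinine[2:6], rep(2.0, 5))  # median(2,1,3)

  # fully observed series pass through bit-identically
  s4 <- make_series(c(1.11, 0.97, 1.42), c(50, 60, 70))
  expect_identical(impute_series(s4)$channels, s4$channels)
})

test_that("imputation never alters observed cells and never edits the mask", {
  for (seed in 1:8) {
    s <- random_series(20, seed + 300, missing = 0.3)
    out <- impute_series(s)
    expect_identical(out$observed_mask, s$observed_mask)
    for (ch in names(s$channels)) {
      obs <- s$observed_mask[, ch]
      expect_identical(out$channels[[ch]][obs], s$channels[[ch]][obs])
      expect_false(anyNA(out$channels[[ch]]))
    }
  }
})

test_that("categorical gaps receive the sentinel code", {
  s <- clinical_series("c", list(icu = c(1, NA, 3)), weight_kg = 70)
  meta <- data.frame(channel = "icu", kind = "categorical", essential = FALSE)
  out <- impute_series(s, preprocess_config(categorical_sentinel = 0),
                       channel_meta = meta)
  expect_equal(out$channels$icu, c(1, 0, 3))
})

test_that("padding masks real steps and refuses to truncate", {
  s6 <- impute_series(make_series(rep(1, 6), rep(60, 6)))
  s48 <- impute_series(make_series(rep(1, 48), rep(60, 48), id = "p2"))
  pb <- pad_and_mask(list(s6, s48), 48)
  expect_equal(rowSums(pb$pad_mask), c(6, 48))
  expect_equal(pb$lengths, c(6L, 48L))
  # round trip recovers the originals exactly
  expect_identical(pb$inputs[1, 1:6, "creatinine"], s6$channels$creatinine)
  expect_identical(pb$inputs[2, , "urine"], s48$channels$urine)
  expect_true(all(pb$inputs[1, 7:48, ] == 0))
  expect_error(pad_and_mask(list(s48), 40), "refusing to truncate")
  pb1 <- pad_and_mask(list(s48))
  expect_true(all(pb1$pad_mask))
})

test_that("masked padded loss equals the per-sequence loss exactly", {
  set.seed(7)
  lengths <- c(4, 9, 6)
  ys <- lapply(lengths, function(L) rbinom(L, 1, 0.5))
  ps <- lapply(lengths, function(L) runif(L, 0.05, 0.95))
  T_max <- max(lengths)
  Y <- matrix(0L, 3, T_max); P <- matrix(0.5, 3, T_max)
  M <- matrix(FALSE, 3, T_max)
  for (b in 1:3) {
    Y[b, seq_len(lengths[b])] <- ys[[b]]
    P[b, seq_len(lengths[b])] <- ps[[b]]
    M[b, seq_len(lengths[b])] <- TRUE
  }
  # flip padded cells arbitrarily: the loss must not move
  P_flip <- P; P_flip[!M] <- 0.99; Y_flip <- Y; Y_flip[!M] <- 1L
  per_seq <- mean(vapply(1:3, function(b) bce_sequence(ys[[b]], ps[[b]]), 1.0))
  expect_equal(bce_sequence(Y, P, M), per_seq, tolerance = 1e-12)
  expect_lt(abs(bce_sequence(Y_flip, P_flip, M) - per_seq), 1e-10)
})

test_that("augmentation with zero strengths is the identity", {
  s <- impute_series(make_series(c(1.2, 1.3, 1.1, 1.4), c(50, 60, 55, 65)))
  cfg0 <- preprocess_config(noise_sd_frac = 0, time_scale_range = c(1, 1),
                            mask_prob = 0)
  set.seed(1)
  expect_identical(augment_series(s, cfg0), s)
})

test_that("time scaling shrinks a linear ramp's slope by the scale factor", {
  T_len <- 40
  s <- clinical_series("ramp", list(ramp = as.numeric(1:T_len)), weight_kg = 70)
  cfg <- preprocess_config(noise_sd_frac = 0, time_scale_range = c(1.1, 1.1),
                           mask_prob = 0)
  out <- augment_series(s, cfg)
  # interior slope (edges are clamped by the grid boundary)
  slopes <- diff(out$channels$ramp[3:35])
  expect_true(all(abs(slopes - 1 / 1.1) < 1e-8))
})

test_that("channel masking replaces non-essential channels everywhere", {
  s <- impute_series(make_series(rep(1.05, 8), rep(60, 8)))
  s$channels$hr <- rnorm(8, 80, 5)
  s$observed_mask <- cbind(s$observed_mask, hr = rep(TRUE, 8))
  meta <- data.frame(channel = c("creatinine", "urine", "hr"),
                     kind = "continuous", essential = c(TRUE, TRUE, FALSE))
  cfg <- preprocess_config(noise_sd_frac = 0, time_scale_range = c(1, 1),
                           mask_prob = 1)
  out <- augment_series(s, cfg, channel_meta = meta)
  expect_identical(out$channels$creatinine, s$channels$creatinine)
  expect_true(all(out$channels$hr == median(s$channels$hr)))
  expect_false(any(out$observed_mask[, "hr"]))
})

test_that("normalisation uses training statistics only", {
  co <- simulate_cohort(sim_config(n_patients = 40, seed = 51))
  co <- impute_cohort(co)
  tr <- cohort_subset(co, 1:30)
  va <- cohort_subset(co, 31:40)
  st <- channel_stats(tr)
  tr_n <- normalize_cohort(tr, st)
  va_n <- normalize_cohort(va, st)
  pool <- function(c_, ch) unlist(lapply(c_$series, function(s) {
    s$channels[[ch]][s$observed_mask[, ch]]
  }))
  expect_lt(abs(mean(pool(tr_n, "creatinine"))), 1e-10)
  expect_equal(sd(pool(tr_n, "creatinine")), 1, tolerance = 1e-10)
  # validation transformed with training stats: hand recomputation
  j <- which(st$channel == "creatinine")
  expect_equal(pool(va_n, "creatinine"),
               (pool(va, "creatinine") - st$mean[j]) / st$sd[j])
  # constant channel: warning, left unscaled
  co2 <- aki_cohort(list(impute_series(make_series(rep(1, 6), rep(60, 6)))),
                    list(static_profile("p1", 40)))
  st2 <- channel_stats(co2)
  w <- capture_warnings(n2 <- normalize_cohort(co2, st2))
  expect_true(length(w) >= 1 && all(grepl("zero variance", w)))
  expect_equal(n2$series[[1]]$channels$creatinine, rep(1, 6))
})
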