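test_that("baseline creatinine is the rolling-window minimum with fallback", {
  s <- make_series(rep(1.0, 48), rep(60, 48))
  expect_equal(compute_baseline_scr(s, 48), 1.0)

  s2 <- make_series(c(1.2, 0.9, 1.4))
  expect_equal(compute_baseline_scr(s2, 3), 0.9)

  # fallback to earliest observed value when the window is empty
  s3 <- make_series(c(1.1, 1.3, NA, NA))
  s3$observed_mask[3:4, "creatinine"] <- FALSE
  thr <- kdigo_thresholds(ratio_window = 2)
  expect_equal(compute_baseline_scr(s3, 4, thr), 1.1)

  s4 <- make_series(rep(NA_real_, 5), rep(60, 5))
  expect_error(compute_baseline_scr(s4, 5), class = "akinet_missing_baseline")
})

test_that("urine rate is hourly volume over body weight", {
  s <- make_series(rep(1, 3), c(35, 0, 28), weight = 70)
  expect_equal(urine_rate_at(s, 1), 0.5)
  expect_equal(urine_rate_at(s, 2), 0)
  expect_equal(urine_rate_at(s, 3), 0.4)
  s$weight_kg <- -1
  expect_error(urine_rate_at(s, 1), class = "akinet_invalid_profile")
})

test_that("creatinine criteria fire at the printed thresholds, inclusively", {
  # 0.3 mg/dL rise within 48 h (inclusive >=)
  creat <- rep(1.0, 48); creat[40] <- 1.3
  y <- label_aki_kdigo(make_series(creat, rep(60, 48)))
  expect_equal(y[40], 1L)
  expect_equal(sum(y), 1L)

  # nothing fires on flat creatinine and adequate urine
  s <- make_series(rep(1.0, 24), rep(0.6 * 70, 24))
  expect_equal(label_aki_kdigo(s), integer(24))

  # 1.5x baseline fires on a slow rise (day 5 at hourly grid length 130)
  creat <- seq(1.0, 1.5, length.out = 130)
  y <- label_aki_kdigo(clinical_series("slow", list(creatinine = creat),
                                       weight_kg = 70))
  expect_equal(y[130], 1L)
  expect_true(any(y == 1L))
})

test_that("oliguria requires strictly more than six consecutive hours", {
  urine <- c(rep(0.4 * 70, 7), rep(60, 3))
  y <- label_aki_kdigo(make_series(rep(1.0, 10), urine))
  expect_equal(y[6], 0L)   # exactly 6 h is not "more than 6 h"
  expect_equal(y[7], 1L)
  # an unobserved hour breaks the run
  s <- make_series(rep(1.0, 10), c(rep(0.4 * 70, 8), rep(60, 2)))
  s$observed_mask[4, "urine"] <- FALSE
  s$channels$urine[4] <- NA
  expect_equal(label_aki_kdigo(s)[8], 0L)
})

test_that("absorbing convention extends labels from first onset", {
  creat <- rep(1.0, 20); creat[10] <- 1.4
  s <- make_series(creat, rep(60, 20))
  y_raw <- label_aki_kdigo(s)
  y_abs <- label_aki_kdigo(s, absorbing = TRUE)
  expect_equal(which(y_raw == 1L)[1], which(y_abs == 1L)[1])
  expect_true(all(y_abs[which(y_abs == 1L)[1]:20] == 1L))
})

test_that("labelling agrees with exhaustive window enumeration", {
  for (seed in 1:25) {
    s <- random_series(sample(6:48, 1), seed)
    expect_equal(label_aki_kdigo(s), oracle_kdigo(s), info = paste("seed", seed))
  }
})

test_that("raising the absolute-rise threshold never creates labels", {
  for (seed in 1:12) {
    s <- random_series(30, seed + 100)
    lo <- label_aki_kdigo(s, kdigo_thresholds(delta_scr = 0.3))
    hi <- label_aki_kdigo(s, kdigo_thresholds(delta_scr = 0.6))
    expect_true(all(hi <= lo))
  }
})

test_that("cohort filters exclude by the stated rules and report counts", {
  mk <- function(id, age = 30, T_len = 24, esrd = FALSE, dial = FALSE,
                 no_scr = FALSE) {
    s <- make_series(rep(1.0, T_len), rep(60, T_len), id = id)
    if (no_scr) {
      s$observed_mask[, "creatinine"] <- FALSE
      s$channels$creatinine[] <- NA
    }
    list(series = s,
         profile = static_profile(id, age = age, esrd_history = esrd,
                                  dialysis_history = dial))
  }
  pats <- list(mk("ok"), mk("young", age = 17), mk("short", T_len = 5),
               mk("esrd", esrd = TRUE), mk("dial", dial = TRUE),
               mk("noscr", no_scr = TRUE))
  co <- aki_cohort(lapply(pats, `[[`, "series"),
                   lapply(pats, `[[`, "profile"))
  res <- apply_cohort_filters(co)
  expect_equal(res$cohort$n, 1L)
  expect_equal(res$cohort$series[[1]]$patient_id, "ok")
  expect_equal(sum(res$report), co$n - res$cohort$n)
  expect_equal(unname(res$report[c("age", "insufficient_steps", "esrd",
                                   "dialysis_history", "missing_baseline")]),
               c(1L, 1L, 1L, 1L, 1L))
  # idempotence
  res2 <- apply_cohort_filters(res$cohort)
  expect_equal(res2$cohort, res$cohort)
  expect_equal(sum(res2$report), 0L)
})

test_that("positives are cropped to the window ending at first onset", {
  creat <- rep(1.0, 40); creat[30:40] <- seq(1.0, 1.6, length.out = 11)
  s <- make_series(creat, rep(60, 40), id = "pos")
  co <- aki_cohort(list(s), list(static_profile("pos", age = 50)))
  res <- apply_cohort_filters(co)
  kept <- res$cohort$series[[1]]
  y <- kept$labels_aki
  expect_equal(y[length(y)], 1L)        # window ends at onset
  expect_true(all(y[-length(y)] == 0L)) # and contains no earlier label
})
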