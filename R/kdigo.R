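#' Rolling baseline serum creatinine
#'
#' The baseline against which the relative KDIGO criterion is judged: the
#' minimum observed creatinine over the trailing `ratio_window` hours
#' (`(t - ratio_window, t]` on the hourly grid). If no creatinine was observed
#' inside that window the earliest observed value of the record is used as a
#' fallback; a record with no observed creatinine at all cannot be baselined
#' and raises a `missing_baseline` condition (such patients are excluded by
#' [apply_cohort_filters()]).
#'
#' @param series A [clinical_series()] with a `creatinine` channel.
#' @param t Step index (1-based hour).
#' @param thresholds A [kdigo_thresholds()].
#' @return Baseline creatinine in mg/dL.
#' @export
compute_baseline_scr <- function(series, t, thresholds = kdigo_thresholds()) {
  scr <- series$channels[["creatinine"]]
  if (is.null(scr)) stop_missing_baseline(series)
  obs <- observed_values(series, "creatinine")
  if (!any(obs)) stop_missing_baseline(series)
  in_win <- obs & series$times > series$times[t] - thresholds$ratio_window &
    series$times <= series$times[t]
  if (any(in_win)) return(min(scr[in_win]))
  scr[which(obs)[1L]]
}

stop_missing_baseline <- function(series) {
  stop(structure(class = c("akinet_missing_baseline", "error", "condition"),
                 list(message = sprintf(
                   "patient %s: no observed creatinine; baseline undefined",
                   series$patient_id), call = sys.call(-1))))
}

# observed indicator for one channel: value present AND mask TRUE
observed_values <- function(series, channel) {
  v <- series$channels[[channel]]
  if (is.null(v)) return(logical(series_length(series)))
  series$observed_mask[, channel] & !is.na(v)
}

#' Weight-normalised urine output rate
#'
#' @param series A [clinical_series()] with a `urine` channel (mL/h) and a
#'   positive `weight_kg`.
#' @param t Step index.
#' @return Urine rate in mL/kg/h at step `t` (`NA` if unobserved).
#' @export
urine_rate_at <- function(series, t) {
  w <- series$weight_kg
  if (!is.finite(w) || w <= 0)
    stop(structure(class = c("akinet_invalid_profile", "error", "condition"),
                   list(message = sprintf("patient %s: missing or nonpositive weight",
                                          series$patient_id), call = sys.call())))
  u <- series$channels[["urine"]]
  if (is.null(u)) stop("series has no urine channel")
  ifelse(observed_values(series, "urine")[t], u[t] / w, NA_real_)
}

#' KDIGO rule-based per-step AKI labelling
#'
#' Applies the binary KDIGO AKI definition on the hourly grid. Step `t` is
#' labelled 1 iff any of:
#' \describe{
#'   \item{absolute rise}{observed creatinine at `t` minus the minimum
#'     observed creatinine within the trailing `delta_window` hours is
#'     `>= delta_scr` (inclusive);}
#'   \item{relative rise}{observed creatinine at `t` is `>= ratio_scr` times
#'     the rolling baseline of [compute_baseline_scr()];}
#'   \item{oliguria}{the weight-normalised urine rate is strictly below
#'     `urine_rate` on a contiguous run of observed hourly steps ending at
#'     `t` whose length exceeds `urine_duration` hours (i.e. at least
#'     `urine_duration + 1` steps).}
#' }
#' Only observed cells participate: an unobserved creatinine at `t` cannot
#' fire the creatinine criteria and an unobserved urine value breaks an
#' oliguria run.
#'
#' @param series A [clinical_series()].
#' @param thresholds A [kdigo_thresholds()].
#' @param absorbing If `TRUE`, labels are monotone-extended so every step at
#'   or after first onset is 1 (first-onset convention). Default `FALSE`
#'   (instantaneous criteria per step).
#' @return Integer vector of per-step labels.
#' @export
label_aki_kdigo <- function(series, thresholds = kdigo_thresholds(),
                            absorbing = FALSE) {
  T_len <- series_length(series)
  scr <- series$channels[["creatinine"]]
  scr_obs <- observed_values(series, "creatinine")
  has_urine <- !is.null(series$channels[["urine"]])
  y <- integer(T_len)

  # oliguria run lengths: consecutive observed steps with rate < threshold
  run <- 0L
  runs <- integer(T_len)
  if (has_urine && is.finite(series$weight_kg) && series$weight_kg > 0) {
    u_obs <- observed_values(series, "urine")
    rate <- series$channels[["urine"]] / series$weight_kg
    for (t in seq_len(T_len)) {
      run <- if (u_obs[t] && rate[t] < thresholds$urine_rate) run + 1L else 0L
      runs[t] <- run
    }
  }

  for (t in seq_len(T_len)) {
    fired <- FALSE
    if (scr_obs[t]) {
      in_delta <- scr_obs & series$times > series$times[t] - thresholds$delta_window &
        series$times <= series$times[t]
      if (any(in_delta) &&
          scr[t] - min(scr[in_delta]) >= thresholds$delta_scr) fired <- TRUE
      if (!fired && any(scr_obs)) {
        base <- compute_baseline_scr(series, t, thresholds)
        if (scr[t] >= thresholds$ratio_scr * base) fired <- TRUE
      }
    }
    if (!fired && runs[t] > thresholds$urine_duration) fired <- TRUE
    y[t] <- as.integer(fired)
  }
  if (absorbing && any(y == 1L)) {
    onset <- which(y == 1L)[1L]
    y[onset:T_len] <- 1L
  }
  y
}

#' Cohort inclusion/exclusion filtering
#'
#' Retains adult patients with enough usable data for temporal modelling:
#' age >= 18; no end-stage renal disease; no dialysis history; a usable
#' baseline creatinine; at least `min_steps` recorded steps; and at least
#' `min_consecutive` consecutive recorded hours prior to first AKI onset
#' (for AKI-negative patients, anywhere before end of record). A step counts
#' as recorded when any channel is observed at it.
#'
#' Retained AKI-positive records are cropped to the (up to) `max_steps`-hour
#' observation window ending at first onset; negatives keep their final
#' `max_steps` hours. Per-step labels are recomputed on each series (via
#' [label_aki_kdigo()]) before filtering if absent.
#'
#' @param cohort An [aki_cohort()].
#' @param thresholds A [kdigo_thresholds()] for labelling where needed.
#' @param min_steps Minimum recorded steps (default 6).
#' @param min_consecutive Minimum consecutive recorded hours pre-onset
#'   (default 12).
#' @param max_steps Observation window cap in steps (default 48).
#' @return A list with `cohort` (the filtered, window-cropped cohort) and
#'   `report`: named integer vector of exclusion counts (one reason per
#'   excluded patient, first failing rule in a fixed order) whose sum equals
#'   the number of patients removed.
#' @export
apply_cohort_filters <- function(cohort, thresholds = kdigo_thresholds(),
                                 min_steps = 6L, min_consecutive = 12L,
                                 max_steps = 48L) {
  reasons <- c("age", "esrd", "dialysis_history", "missing_baseline",
               "insufficient_steps", "insufficient_consecutive")
  report <- stats::setNames(integer(length(reasons)), reasons)
  keep <- logical(cohort$n)
  cropped <- vector("list", cohort$n)

  for (i in seq_len(cohort$n)) {
    s <- cohort$series[[i]]
    p <- cohort$profiles[[i]]
    fail <- NULL
    if (p$age < 18) fail <- "age"
    else if (p$esrd_history) fail <- "esrd"
    else if (p$dialysis_history) fail <- "dialysis_history"
    else if (!p$baseline_scr_available || !any(observed_values(s, "creatinine")))
      fail <- "missing_baseline"
    else {
      recorded <- rowSums(s$observed_mask) > 0
      if (sum(recorded) < min_steps) fail <- "insufficient_steps"
      else {
        if (is.null(s$labels_aki)) s$labels_aki <- label_aki_kdigo(s, thresholds)
        onset <- if (any(s$labels_aki == 1L)) which(s$labels_aki == 1L)[1L] else NA_integer_
        horizon <- if (is.na(onset)) length(recorded) else onset - 1L
        if (longest_run(recorded[seq_len(max(horizon, 0L))]) < min_consecutive)
          fail <- "insufficient_consecutive"
      }
    }
    if (is.null(fail)) {
      keep[i] <- TRUE
      onset <- if (any(s$labels_aki == 1L)) which(s$labels_aki == 1L)[1L] else NA_integer_
      anchor <- if (is.na(onset)) series_length(s) else onset
      from <- max(1L, anchor - max_steps + 1L)
      cropped[[i]] <- crop_series(s, from, anchor)
    } else {
      report[fail] <- report[fail] + 1L
    }
  }
  out <- aki_cohort(cropped[keep], cohort$profiles[keep], cohort$channel_meta)
  if (out$n == 0L) warning("cohort is empty after filtering")
  list(cohort = out, report = report)
}

longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

crop_series <- function(series, from, to) {
  idx <- from:to
  out <- series
  out$times <- seq_along(idx)
  out$channels <- lapply(series$channels, function(v) v[idx])
  out$observed_mask <- series$observed_mask[idx, , drop = FALSE]
  if (!is.null(series$labels_aki)) out$labels_aki <- series$labels_aki[idx]
  out
}

#' Write per-step label table and exclusion report
#'
#' @param cohort A labelled [aki_cohort()].
#' @param path Output path for the delimited label table
#'   (columns `patient_id`, `hour`, `y`).
#' @export
write_label_table <- function(cohort, path) {
  rows <- lapply(cohort$series, function(s) {
    data.frame(patient_id = s$patient_id, hour = s$times,
               y = if (is.null(s$labels_aki)) NA_integer_ else s$labels_aki)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_table
#' @param report Exclusion-count vector from [apply_cohort_filters()].
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE)
  invisible(path)
}
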