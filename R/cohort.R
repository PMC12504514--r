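#' Clinical time series for one patient
#'
#' Container for one patient's hourly multichannel observations. Values are
#' stored per channel on a 1-based hourly step grid; `observed_mask` records
#' which cells were actually measured (imputation fills values but never
#' touches the mask). Unobserved cells hold `NA` until imputed.
#'
#' @param patient_id Character scalar identifier.
#' @param channels Named list of numeric vectors, one per channel, all of the
#'   same length `T`. Conventional channel names used by the KDIGO engine are
#'   `"creatinine"` (serum creatinine, mg/dL) and `"urine"` (urine output,
#'   mL/h).
#' @param observed_mask Logical matrix (`T x n_channels`, columns named as
#'   `channels`); `TRUE` marks a measured cell. Defaults to `!is.na(value)`.
#' @param labels_aki Optional integer vector of per-step binary AKI labels.
#' @param weight_kg Positive scalar body weight in kilograms.
#' @param times Integer vector of hour indices; defaults to `1:T`. Must be
#'   strictly increasing with unit spacing.
#'
#' @return An object of class `"clinical_series"`.
#' @export
clinical_series <- function(patient_id, channels, observed_mask = NULL,
                            labels_aki = NULL, weight_kg = NA_real_,
                            times = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  T_len <- length(channels[[1L]])
  if (!all(vapply(channels, length, 1L) == T_len))
    stop("all channels must share the same length")
  if (is.null(times)) times <- seq_len(T_len)
  if (T_len > 1L && any(diff(times) != 1L))
    stop("times must be strictly increasing with unit (hourly) spacing")
  if (is.null(observed_mask)) {
    observed_mask <- !vapply(channels, is.na, logical(T_len))
    if (T_len == 1L) observed_mask <- matrix(observed_mask, nrow = 1L,
                                             dimnames = list(NULL, names(channels)))
  }
  observed_mask <- as.matrix(observed_mask)
  colnames(observed_mask) <- names(channels)
  if (nrow(observed_mask) != T_len || ncol(observed_mask) != length(channels))
    stop("observed_mask must be T x n_channels")
  if (!is.null(labels_aki)) {
    labels_aki <- as.integer(labels_aki)
    if (length(labels_aki) != T_len) stop("labels_aki must have one entry per step")
    if (!all(labels_aki %in% c(0L, 1L))) stop("labels_aki must be binary")
  }
  structure(list(patient_id = patient_id, times = as.integer(times),
                 channels = lapply(channels, as.numeric),
                 observed_mask = observed_mask,
                 labels_aki = labels_aki, weight_kg = as.numeric(weight_kg)),
            class = "clinical_series")
}

#' @export
print.clinical_series <- function(x, ...) {
  cat(sprintf("<clinical_series> patient %s: T = %d steps, %d channels (%s)\n",
              x$patient_id, length(x$times), length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$labels_aki))
    cat(sprintf("  AKI label: %d positive step(s)\n", sum(x$labels_aki)))
  invisible(x)
}

series_length <- function(series) length(series$times)

#' Static patient profile
#'
#' Non-temporal covariates, exclusion-history flags, and the three patient
#' level outcome targets (AKI onset, renal recovery, dialysis requirement)
#' used by the multi-task heads.
#'
#' @param patient_id Character id matching a [clinical_series()].
#' @param age Age in years.
#' @param sex `"F"`, `"M"` or other category label.
#' @param comorbidities Named numeric/logical vector of binary flags.
#' @param esrd_history,dialysis_history Logical exclusion-history flags.
#' @param baseline_scr_available Logical; `FALSE` marks a chart with no usable
#'   baseline creatinine.
#' @param outcome_aki,outcome_recovery,outcome_dialysis Binary outcomes.
#'
#' @return An object of class `"static_profile"`.
#' @export
static_profile <- function(patient_id, age, sex = "F",
                           comorbidities = numeric(0),
                           esrd_history = FALSE, dialysis_history = FALSE,
                           baseline_scr_available = TRUE,
                           outcome_aki = 0L, outcome_recovery = 0L,
                           outcome_dialysis = 0L) {
  stopifnot(age >= 0)
  stopifnot(outcome_aki %in% 0:1, outcome_recovery %in% 0:1,
            outcome_dialysis %in% 0:1)
  structure(list(patient_id = patient_id, age = as.numeric(age), sex = sex,
                 comorbidities = comorbidities,
                 esrd_history = isTRUE(esrd_history),
                 dialysis_history = isTRUE(dialysis_history),
                 baseline_scr_available = isTRUE(baseline_scr_available),
                 outcome_aki = as.integer(outcome_aki),
                 outcome_recovery = as.integer(outcome_recovery),
                 outcome_dialysis = as.integer(outcome_dialysis)),
            class = "static_profile")
}

#' KDIGO decision thresholds
#'
#' The rule constants of the KDIGO AKI definition: an absolute serum
#' creatinine rise of `delta_scr` mg/dL within `delta_window` hours, a rise to
#' `ratio_scr` times the baseline (rolling minimum over `ratio_window` hours),
#' or urine output below `urine_rate` mL/kg/h for more than `urine_duration`
#' consecutive hours.
#'
#' @param delta_scr Absolute creatinine rise threshold (mg/dL); default 0.3.
#' @param delta_window Lookback for the absolute rise (hours); default 48.
#' @param ratio_scr Relative rise threshold; default 1.5.
#' @param ratio_window Baseline lookback (hours); default 168 (7 days).
#' @param urine_rate Oliguria threshold (mL/kg/h); default 0.5.
#' @param urine_duration Oliguria must persist strictly longer than this many
#'   hours; default 6.
#'
#' @return An object of class `"kdigo_thresholds"`.
#' @export
kdigo_thresholds <- function(delta_scr = 0.3, delta_window = 48,
                             ratio_scr = 1.5, ratio_window = 168,
                             urine_rate = 0.5, urine_duration = 6) {
  vals <- c(delta_scr, delta_window, ratio_scr, ratio_window,
            urine_rate, urine_duration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all KDIGO thresholds must be strictly positive")
  structure(list(delta_scr = delta_scr, delta_window = delta_window,
                 ratio_scr = ratio_scr, ratio_window = ratio_window,
                 urine_rate = urine_rate, urine_duration = urine_duration),
            class = "kdigo_thresholds")
}

#' Cohort of clinical series with aligned static profiles
#'
#' @param series List of [clinical_series()] objects.
#' @param profiles List of [static_profile()] objects, aligned one-to-one with
#'   `series` (matching `patient_id`).
#' @param channel_meta Data frame with columns `channel`, `kind` (one of
#'   `"continuous"`, `"binary"`, `"categorical"`) and `essential` (logical;
#'   essential channels feed the KDIGO rules and are never mask-augmented).
#'   Defaults to all-continuous, with `creatinine` and `urine` essential.
#'
#' @return An object of class `"aki_cohort"` with fields `series`, `profiles`,
#'   `channel_meta`, `n` (patients) and `d` (channels).
#' @export
aki_cohort <- function(series, profiles, channel_meta = NULL) {
  stopifnot(is.list(series), is.list(profiles),
            length(series) == length(profiles))
  ids_s <- vapply(series, function(s) s$patient_id, "")
  ids_p <- vapply(profiles, function(p) p$patient_id, "")
  if (!identical(ids_s, ids_p))
    stop("series and profiles must be aligned by patient_id")
  ch <- if (length(series)) names(series[[1L]]$channels) else character(0)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(channel = ch,
                               kind = rep("continuous", length(ch)),
                               essential = ch %in% c("creatinine", "urine"),
                               stringsAsFactors = FALSE)
  }
  structure(list(series = series, profiles = profiles,
                 channel_meta = channel_meta,
                 n = length(series), d = length(ch)),
            class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  pos <- sum(vapply(x$profiles, function(p) p$outcome_aki, 1L))
  cat(sprintf("<aki_cohort> %d patients, %d channels; AKI-positive: %d (%.1f%%)\n",
              x$n, x$d, pos, if (x$n) 100 * pos / x$n else 0))
  invisible(x)
}

#' Subset a cohort by patient index
#' @param cohort An [aki_cohort()].
#' @param idx Integer index vector.
#' @return The subset cohort.
#' @export
cohort_subset <- function(cohort, idx) {
  aki_cohort(cohort$series[idx], cohort$profiles[idx], cohort$channel_meta)
}
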