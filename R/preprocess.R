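#' Preprocessing configuration
#'
#' @param ffill_max_gap Longest missing run (steps) still treated as a
#'   short-term gap and filled by carry-forward/carry-backward; longer runs
#'   fall through to statistical imputation. Default 3 (a conservative
#'   clinical carry-forward horizon).
#' @param categorical_sentinel Code assigned to missing categorical entries.
#' @param statistic Patient-level statistic for persistent gaps, `"median"`
#'   (default, robust) or `"mean"`.
#' @param noise_sd_frac Augmentation noise SD as a fraction of the channel SD.
#' @param time_scale_range Range of the elastic temporal scaling factor.
#' @param mask_prob Per-channel probability that a non-essential channel is
#'   masked during augmentation.
#' @param normalize Whether continuous channels are z-scored.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(ffill_max_gap = 3L, categorical_sentinel = 0,
                              statistic = c("median", "mean"),
                              noise_sd_frac = 0.05,
                              time_scale_range = c(0.9, 1.1),
                              mask_prob = 0.1, normalize = TRUE) {
  stopifnot(ffill_max_gap >= 1L, mask_prob >= 0, mask_prob <= 1,
            noise_sd_frac >= 0, diff(time_scale_range) >= 0,
            time_scale_range[1] > 0)
  structure(list(ffill_max_gap = as.integer(ffill_max_gap),
                 categorical_sentinel = categorical_sentinel,
                 statistic = match.arg(statistic),
                 noise_sd_frac = noise_sd_frac,
                 time_scale_range = time_scale_range,
                 mask_prob = mask_prob, normalize = isTRUE(normalize)),
            class = "preprocess_config")
}

# fill missing runs of length <= cap forward from the previous observation,
# then backward from the next (covers leading runs); longer runs untouched
ffill_bfill <- function(x, cap) {
  n <- length(x)
  miss <- is.na(x)
  if (!any(miss) || all(miss)) return(x)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > cap) next
    a <- starts[k]; b <- ends[k]
    if (a > 1L) x[a:b] <- x[a - 1L]          # forward
    else if (b < n) x[a:b] <- x[b + 1L]      # leading run: backward
  }
  x
}

#' Impute one clinical series
#'
#' Short gaps (runs of at most `ffill_max_gap` missing steps) in continuous
#' and binary channels are carry-filled forward then backward; remaining
#' gaps receive the patient-level median (or mean) of observed values,
#' falling back to the cohort-level statistic in `cohort_stats`. Missing
#' categorical entries are set to the sentinel code. `observed_mask` is
#' never modified, so the original missingness pattern stays available to
#' the model and the labeller.
#'
#' @param series A [clinical_series()].
#' @param config A [preprocess_config()].
#' @param channel_meta Channel kind table (as in [aki_cohort()]); defaults
#'   to treating every channel as continuous.
#' @param cohort_stats Optional named vector of cohort-level fallback values
#'   per channel.
#' @return The imputed series.
#' @export
impute_series <- function(series, config = preprocess_config(),
                          channel_meta = NULL, cohort_stats = NULL) {
  stat_fun <- if (config$statistic == "median") stats::median else mean
  kinds <- channel_kinds(names(series$channels), channel_meta)
  for (ch in names(series$channels)) {
    v <- series$channels[[ch]]
    v[!series$observed_mask[, ch]] <- NA_real_
    if (kinds[[ch]] == "categorical") {
      v[is.na(v)] <- config$categorical_sentinel
    } else {
      v <- ffill_bfill(v, config$ffill_max_gap)
      if (anyNA(v)) {
        fill <- stat_fun(v, na.rm = TRUE)
        if (!is.finite(fill)) fill <- cohort_stats[[ch]] %||% NA_real_
        if (!is.finite(fill)) {
          warning(sprintf("channel %s has no observed values anywhere; filled with 0", ch))
          fill <- 0
        }
        v[is.na(v)] <- fill
      }
      if (kinds[[ch]] == "binary") v <- floor(v + 0.5)
    }
    series$channels[[ch]] <- v
  }
  series
}

`%||%` <- function(a, b) if (is.null(a)) b else a

channel_kinds <- function(channels, channel_meta) {
  kinds <- stats::setNames(rep("continuous", length(channels)), channels)
  if (!is.null(channel_meta))
    kinds[channel_meta$channel] <- channel_meta$kind
  as.list(kinds)
}

#' Impute a whole cohort
#'
#' Cohort-level fallback statistics are computed from the observed cells of
#' `stats_cohort` (pass the training split so no information leaks from
#' validation or test patients) and applied to every series.
#'
#' @param cohort An [aki_cohort()].
#' @param config A [preprocess_config()].
#' @param stats_cohort Cohort whose observed values define the fallback
#'   statistic; defaults to `cohort` itself.
#' @return The imputed cohort.
#' @export
impute_cohort <- function(cohort, config = preprocess_config(),
                          stats_cohort = cohort) {
  stat_fun <- if (config$statistic == "median") stats::median else mean
  ch_names <- cohort$channel_meta$channel
  pooled <- stats::setNames(lapply(ch_names, function(ch) {
    unlist(lapply(stats_cohort$series, function(s) {
      s$channels[[ch]][observed_values(s, ch)]
    }))
  }), ch_names)
  cohort_stats <- vapply(pooled, function(v)
    if (length(v)) stat_fun(v) else NA_real_, 1.0)
  cohort$series <- lapply(cohort$series, impute_series, config = config,
                          channel_meta = cohort$channel_meta,
                          cohort_stats = as.list(cohort_stats))
  cohort
}

#' Per-channel normalisation statistics
#'
#' Means and SDs of the observed cells of every continuous channel, computed
#' on the training split only.
#'
#' @param cohort An [aki_cohort()] (training split).
#' @return Data frame with `channel`, `mean`, `sd`.
#' @export
channel_stats <- function(cohort) {
  meta <- cohort$channel_meta
  rows <- lapply(seq_len(nrow(meta)), function(j) {
    ch <- meta$channel[j]
    v <- unlist(lapply(cohort$series, function(s)
      s$channels[[ch]][observed_values(s, ch)]))
    data.frame(channel = ch, kind = meta$kind[j],
               mean = if (length(v)) mean(v) else 0,
               sd = if (length(v) > 1) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Z-score continuous channels with training-split statistics
#'
#' Binary and categorical channels pass through untouched; a zero-variance
#' channel is left unscaled with a warning.
#'
#' @param cohort An [aki_cohort()].
#' @param stats Output of [channel_stats()] on the training split.
#' @return The normalised cohort.
#' @export
normalize_cohort <- function(cohort, stats) {
  for (j in seq_len(nrow(stats))) {
    if (stats$kind[j] != "continuous") next
    ch <- stats$channel[j]
    if (stats$sd[j] <= 0) {
      warning(sprintf("channel %s has zero variance; left unscaled", ch))
      next
    }
    for (i in seq_len(cohort$n)) {
      cohort$series[[i]]$channels[[ch]] <-
        (cohort$series[[i]]$channels[[ch]] - stats$mean[j]) / stats$sd[j]
    }
  }
  cohort
}

#' Pad variable-length series into a batch with a step mask
#'
#' Right-pads every sequence to `T_max` with zeros and records which steps
#' are real in `pad_mask`; padded positions contribute nothing to any loss,
#' and unpadding recovers the originals exactly.
#'
#' @param series_list List of (imputed) [clinical_series()].
#' @param T_max Padded length; defaults to the longest series.
#' @return An object of class `"padded_batch"`: `inputs` (`B x T_max x d`),
#'   `pad_mask` (`B x T_max`, `TRUE` = real step), `labels` (`B x T_max`),
#'   `lengths`, and `channels` (column names).
#' @export
pad_and_mask <- function(series_list, T_max = NULL) {
  lengths <- vapply(series_list, series_length, 1L)
  if (is.null(T_max)) T_max <- max(lengths)
  if (any(lengths > T_max))
    stop(sprintf("sequence of length %d exceeds T_max = %d; refusing to truncate",
                 max(lengths), T_max))
  B <- length(series_list)
  ch <- names(series_list[[1L]]$channels)
  d <- length(ch)
  inputs <- array(0, c(B, T_max, d), dimnames = list(NULL, NULL, ch))
  labels <- matrix(0L, B, T_max)
  pad_mask <- matrix(FALSE, B, T_max)
  for (i in seq_len(B)) {
    s <- series_list[[i]]
    Ti <- lengths[i]
    for (j in seq_len(d)) inputs[i, seq_len(Ti), j] <- s$channels[[j]]
    if (!is.null(s$labels_aki)) labels[i, seq_len(Ti)] <- s$labels_aki
    pad_mask[i, seq_len(Ti)] <- TRUE
  }
  structure(list(inputs = inputs, pad_mask = pad_mask, labels = labels,
                 lengths = lengths, channels = ch),
            class = "padded_batch")
}

#' Train-time augmentation of one series
#'
#' Applies, in order: elastic temporal scaling by a factor drawn from
#' `time_scale_range` (values are linearly resampled back onto the original
#' hourly grid, so length and the label grid are preserved); additive
#' Gaussian noise on continuous channels with SD equal to
#' `noise_sd_frac` times the channel's observed SD; and independent masking
#' of each non-essential channel with probability `mask_prob` (masked
#' channels are set to the patient median, or the sentinel for categorical
#' channels, with their mask cleared). Labels are never touched. Uses the
#' session RNG; seed upstream for reproducibility.
#'
#' @param series An imputed [clinical_series()].
#' @param config A [preprocess_config()].
#' @param channel_meta Channel kind/essential table.
#' @return The augmented series.
#' @export
augment_series <- function(series, config = preprocess_config(),
                           channel_meta = NULL) {
  kinds <- channel_kinds(names(series$channels), channel_meta)
  essential <- stats::setNames(
    names(series$channels) %in% c("creatinine", "urine"),
    names(series$channels))
  if (!is.null(channel_meta))
    essential[channel_meta$channel] <- channel_meta$essential
  T_len <- series_length(series)
  s_factor <- stats::runif(1, config$time_scale_range[1],
                           config$time_scale_range[2])
  for (ch in names(series$channels)) {
    v <- series$channels[[ch]]
    if (kinds[[ch]] == "continuous" && !anyNA(v)) {
      if (s_factor != 1 && T_len > 1)
        v <- stats::approx(seq_len(T_len), v, xout = seq_len(T_len) / s_factor,
                           rule = 2)$y
      if (config$noise_sd_frac > 0) {
        sdv <- stats::sd(series$channels[[ch]])
        if (is.finite(sdv) && sdv > 0)
          v <- v + stats::rnorm(T_len, 0, config$noise_sd_frac * sdv)
      }
    }
    series$channels[[ch]] <- v
  }
  for (ch in names(series$channels)) {
    if (essential[[ch]]) next
    if (stats::runif(1) < config$mask_prob) {
      series$channels[[ch]] <- rep(
        if (kinds[[ch]] == "categorical") config$categorical_sentinel
        else stats::median(series$channels[[ch]]), T_len)
      series$observed_mask[, ch] <- FALSE
    }
  }
  series
}
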