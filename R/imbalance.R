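#' Hybrid resampling plan with exact class bookkeeping
#'
#' Computes the before/after class table for SMOTE-plus-undersampling.
#' With `fixed_total = TRUE` (the default) the cohort size is held fixed:
#' synthetic minority additions are exactly offset by random removals from
#' the majority. The target is either a positive-class fraction or a
#' majority:minority ratio (`1:ratio` format, give the scalar `ratio`).
#' Counts are rounded half-up; reported prevalence uses 1 decimal and the
#' ratio 2 decimals.
#'
#' @param n_pos,n_neg Before-counts of the positive (minority) and negative
#'   classes.
#' @param target_prevalence Target positive fraction (exclusive with
#'   `target_ratio`).
#' @param target_ratio Target majority:minority quotient `N_neg / N_pos`.
#' @param fixed_total Keep the total count fixed (default `TRUE`).
#' @param k_neighbors SMOTE neighbourhood size (default 5).
#' @param seed RNG seed used when the plan is applied.
#' @return An object of class `"resampling_plan"` with before/after counts,
#'   `n_synthetic`, `n_undersampled`, `prevalence_after_pct` (1 decimal) and
#'   `ratio_after` (2 decimals).
#' @export
resampling_plan <- function(n_pos, n_neg, target_prevalence = NULL,
                            target_ratio = NULL, fixed_total = TRUE,
                            k_neighbors = 5L, seed = 1L) {
  if (is.null(target_prevalence) == is.null(target_ratio))
    stop("give exactly one of target_prevalence or target_ratio")
  half_up <- function(x) floor(x + 0.5)
  total <- n_pos + n_neg
  if (fixed_total) {
    n_pos_after <- if (!is.null(target_ratio)) half_up(total / (1 + target_ratio))
                   else half_up(target_prevalence * total)
    n_neg_after <- total - n_pos_after
  } else {
    n_neg_after <- n_neg
    n_pos_after <- if (!is.null(target_ratio)) half_up(n_neg / target_ratio)
                   else half_up(target_prevalence / (1 - target_prevalence) * n_neg)
  }
  n_synth <- n_pos_after - n_pos
  n_under <- n_neg - n_neg_after
  if (n_synth < 0 || n_under < 0)
    stop(sprintf(paste("infeasible plan: would need %d synthetic positives and",
                       "%d removed negatives"), n_synth, n_under))
  total_after <- n_pos_after + n_neg_after
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 n_pos_after = n_pos_after, n_neg_after = n_neg_after,
                 total = total, total_after = total_after,
                 n_synthetic = n_synth, n_undersampled = n_under,
                 prevalence_before_pct = round(100 * n_pos / total, 1),
                 prevalence_after_pct = round(100 * n_pos_after / total_after, 1),
                 ratio_before = round(n_neg / n_pos, 2),
                 ratio_after = round(n_neg_after / n_pos_after, 2),
                 fixed_total = fixed_total,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("resampling plan: %d/%d (%.1f%%) -> %d/%d (%.1f%%), ratio 1:%.2f\n",
              x$n_pos, x$total, x$prevalence_before_pct,
              x$n_pos_after, x$total_after, x$prevalence_after_pct,
              x$ratio_after))
  cat(sprintf("  %d synthetic positives (SMOTE, k = %d), %d negatives removed\n",
              x$n_synthetic, x$k_neighbors, x$n_undersampled))
  invisible(x)
}

#' SMOTE interpolation between a minority point and a neighbour
#'
#' `x + lambda * (x_neighbor - x)`: a point on the segment between the two.
#'
#' @param x,x_neighbor Feature vectors of equal length.
#' @param lambda Interpolation draw in `[0, 1]` (uniform at sampling time).
#' @return The synthetic feature vector.
#' @export
smote_interpolate <- function(x, x_neighbor, lambda) {
  if (length(x) != length(x_neighbor)) stop("dimension mismatch")
  x + lambda * (x_neighbor - x)
}

#' Within-class Euclidean nearest neighbours
#'
#' Brute-force k-nearest-neighbour indices within the minority class
#' (self excluded; zero-distance duplicates allowed). If the class has at
#' most `k` members, `k` is reduced with a warning.
#'
#' @param X Matrix (`n_min x p`) of minority feature vectors.
#' @param k Neighbourhood size.
#' @return Integer matrix `n_min x k` of neighbour row indices, nearest
#'   first.
#' @export
minority_neighbors <- function(X, k = 5L) {
  n <- nrow(X)
  if (n < 2L) stop("need at least two minority points")
  if (k >= n) {
    warning(sprintf("k = %d >= class size %d; reduced to %d", k, n, n - 1L))
    k <- n - 1L
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nb <- apply(D, 1, function(row) order(row)[seq_len(k)])
  if (k == 1L) matrix(nb, ncol = 1L) else t(nb)
}

#' Apply a hybrid SMOTE/undersampling plan to a cohort
#'
#' Operates on the training split only (pass that split in). Sequences are
#' imputed, normalised, padded to a common length and flattened (static
#' profile features appended) to form the SMOTE feature space; synthetic
#' minority patients are linear interpolations of a base patient and one of
#' its k nearest minority neighbours, reshaped back into sequences of the
#' base patient's length, inheriting the base patient's labels, outcomes and
#' profile. The majority class is then randomly undersampled without
#' replacement to meet the plan. Fully deterministic given the plan seed.
#'
#' @param cohort An [aki_cohort()] (training split, labelled).
#' @param plan A [resampling_plan()]; defaults to balancing to 50%.
#' @param preprocess A [preprocess_config()] for the feature-space build.
#' @return List with `cohort` (resampled) and `plan`.
#' @export
hybrid_resample <- function(cohort, plan = NULL,
                            preprocess = preprocess_config()) {
  pos_idx <- which(vapply(cohort$profiles, function(p) p$outcome_aki, 1L) == 1L)
  neg_idx <- setdiff(seq_len(cohort$n), pos_idx)
  if (!length(pos_idx) || !length(neg_idx))
    stop("hybrid_resample needs both classes present")
  if (is.null(plan))
    plan <- resampling_plan(length(pos_idx), length(neg_idx),
                            target_prevalence = 0.5)
  if (plan$n_pos != length(pos_idx) || plan$n_neg != length(neg_idx))
    stop("plan before-counts do not match the cohort")
  if (plan$n_synthetic == 0L && plan$n_undersampled == 0L)
    return(list(cohort = cohort, plan = plan))

  with_seed(plan$seed, {
    synth <- list()
    if (plan$n_synthetic > 0L) {
      imp <- impute_cohort(cohort, preprocess)
      st <- channel_stats(cohort_subset(imp, seq_len(imp$n)))
      norm <- normalize_cohort(imp, st)
      T_max <- max(vapply(norm$series, series_length, 1L))
      pb <- pad_and_mask(norm$series[pos_idx], T_max)
      flat <- cbind(matrix(pb$inputs, nrow = length(pos_idx)),
                    profile_matrix(norm$profiles[pos_idx]))
      nb <- minority_neighbors(flat, plan$k_neighbors)
      base_orig <- impute_cohort(cohort, preprocess)  # original scale
      pb_orig <- pad_and_mask(base_orig$series[pos_idx], T_max)
      for (s in seq_len(plan$n_synthetic)) {
        b <- sample(length(pos_idx), 1L)
        j <- nb[b, sample(ncol(nb), 1L)]
        lam <- stats::runif(1)
        Ti <- pb_orig$lengths[b]
        ov <- seq_len(min(Ti, pb_orig$lengths[j]))  # overlapping real steps
        new_ser <- base_orig$series[[pos_idx[b]]]
        for (ci in seq_along(new_ser$channels)) {
          vb <- pb_orig$inputs[b, seq_len(Ti), ci]
          vj <- pb_orig$inputs[j, ov, ci]
          kind <- cohort$channel_meta$kind[ci]
          vv <- vb
          vv[ov] <- smote_interpolate(vb[ov], vj, lam)
          if (kind == "binary") vv <- floor(vv + 0.5)
          if (kind == "categorical") { vv <- vb; if (lam >= 0.5) vv[ov] <- vj }
          new_ser$channels[[ci]] <- vv
        }
        new_ser$weight_kg <- smote_interpolate(base_orig$series[[pos_idx[b]]]$weight_kg,
                                               base_orig$series[[pos_idx[j]]]$weight_kg, lam)
        new_ser$patient_id <- sprintf("synthetic_%05d", s)
        new_prof <- cohort$profiles[[pos_idx[b]]]
        new_prof$patient_id <- new_ser$patient_id
        synth[[s]] <- list(series = new_ser, profile = new_prof)
      }
    }
    keep_neg <- if (plan$n_undersampled > 0L)
      sort(sample(neg_idx, plan$n_neg_after)) else neg_idx
    keep <- sort(c(pos_idx, keep_neg))
    series <- c(cohort$series[keep], lapply(synth, `[[`, "series"))
    profiles <- c(cohort$profiles[keep], lapply(synth, `[[`, "profile"))
    out <- aki_cohort(series, profiles, cohort$channel_meta)
  })
  list(cohort = out, plan = plan)
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# numeric static-profile design matrix used as model context and SMOTE tail
profile_matrix <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    c(age = (p$age - 60) / 20, male = as.numeric(p$sex == "M"),
      p$comorbidities)
  })
  do.call(rbind, rows)
}
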