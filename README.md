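# akinet

Early-warning modelling of acute kidney injury (AKI) from hourly ICU time
series, in base R.

AKI is defined operationally by the KDIGO consensus rules — serum creatinine
rising ≥ 0.3 mg/dL within 48 h, reaching ≥ 1.5× the 7-day baseline, or urine
output < 0.5 mL/kg/h for more than 6 h — but creatinine lags the injury.
`akinet` is for quantitative clinical researchers who want to prototype and
stress-test dynamic AKI risk models without access-restricted EHR data. It
provides the full pipeline:

* **KDIGO rule engine** — per-step labelling (`label_aki_kdigo()`), rolling
  baseline creatinine, and cohort inclusion filters (age ≥ 18, no
  ESRD/dialysis history, ≥ 6 recorded steps, ≥ 12 consecutive hours before
  onset) with an exclusion report.
* **Synthetic cohorts** — `simulate_cohort()` plants a pre-onset creatinine
  drift and urine-rate decline in AKI-positive patients and labels the
  generated trajectories with the same KDIGO engine, with configurable
  prevalence, missingness and correlated recovery/dialysis outcomes.
* **Preprocessing** — carry-forward/backward imputation with a gap cap,
  patient-median fallback, z-scoring with training-split statistics,
  padding/masking of variable-length sequences, and train-time augmentation
  (noise, elastic time scaling, channel masking).
* **The model** — an LSTM encoder

  h_t = o_t ⊙ tanh(c_t),  c_t = f_t ⊙ c_{t−1} + i_t ⊙ g_t,

  with either a per-step risk head ŷ(t) = σ(w·h_t + b) trained on the
  masked sequence cross-entropy plus a temporal smoothness penalty
  γ Σ (ŷ_t − ŷ_{t−1})², or temporal attention
  α_t = softmax(vᵀ tanh(W_h h_t + b_h)), c = Σ α_t h_t (the query v
  optionally personalised from the static profile) with an entropy
  regulariser, plus three multi-task outcome heads with optional
  uncertainty weighting Σ L_k/(2σ_k²) + log σ_k. All gradients analytic.
* **Imbalance machinery** — inverse-class-frequency and accuracy-driven
  dynamic weights, (α-balanced) focal loss, and SMOTE hybrid resampling
  with exact class bookkeeping (`resampling_plan()`, `hybrid_resample()`).
* **Runtime** — plain SGD (lr 0.001, /10 every 10 epochs, batches of 32),
  seeded splits, rank-statistic AUC metrics, component ablations
  (`ablate()`), and elastic-anchored dynamic evaluation at inference
  (`dynamic_evaluate()`).

## Worked example

```r
library(akinet)

cfg <- sim_config(n_patients = 300, target_prevalence = 0.30,
                  signal_effect = 1.0, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <aki_cohort> 300 patients, 7 channels; AKI-positive: 99 (33.0%)

filtered <- apply_cohort_filters(cohort)
filtered$report
#>                      age                     esrd         dialysis_history
#>                        0                        0                        0
#>         missing_baseline       insufficient_steps insufficient_consecutive
#>                        0                        0                       21

# inverse-frequency weights for the rare positive steps
y <- unlist(lapply(filtered$cohort$series, function(s) s$labels_aki))
w <- inverse_class_weights(c(sum(y == 0), sum(y == 1)))
round(w, 2)
#> [1]  0.50 57.13

fit <- akinet(cohort, mode = "sequence",
              loss = loss_config(data_loss = "weighted", class_weights = w,
                                 l2_lambda = 1e-4),
              train = train_config(epochs = 10, d_h = 32, d_a = 16, seed = 42,
                                   split = c(0.70, 0.15, 0.15)),
              resample = TRUE)
summary(fit)
#> AKI risk model (sequence mode)
#>   encoder: LSTM d = 7 -> d_h = 32; attention width 16
#>   trained 10 epochs (SGD, lr0 = 0.001); best epoch 4, validation AUC 0.820
#>   cohort: 279 patients (train 195 / val 41 / test 43)
#> held-out test split: n = 43  accuracy 0.535  recall 0.929  F1 0.565  AUC 0.771
```

The 21 excluded patients lacked 12 consecutive recorded hours before their
first labelled onset. The fitted object supports `predict()` (per-step
risks, patient scores, task-head probabilities, attention weights),
`coef()`, `residuals()` and `plot()` (training curves). A patient's score
is the model's risk at the final observed hour of their window.

Class-rebalancing bookkeeping reproduces published cohort tables exactly
from the before-counts and target:

```r
resampling_plan(3812, 27963 - 3812, target_prevalence = 0.471)
#> resampling plan: 3812/27963 (13.6%) -> 13171/27963 (47.1%), ratio 1:1.12
#>   9359 synthetic positives (SMOTE, k = 5), 9359 negatives removed
```

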