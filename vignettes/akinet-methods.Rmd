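---
title: "Modelling early acute kidney injury risk from hourly ICU time series"
author: "akinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early acute kidney injury risk from hourly ICU time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akinet)
```

## The problem

Acute kidney injury (AKI) in intensive care is defined operationally by the
KDIGO consensus rules: a serum creatinine rise of at least 0.3 mg/dL within
48 hours, a rise to at least 1.5 times the 7-day baseline, or urine output
below 0.5 mL/kg/h for more than 6 hours. Because creatinine is a lagging
marker, a model that watches the hourly trajectory of creatinine, urine
output and vital signs can flag rising risk before the formal definition is
met. `akinet` implements such an early-warning model end to end: rule-based
labelling, cohort filtering, imputation and augmentation, an LSTM encoder
with temporal attention, cost-sensitive and resampling machinery for the
heavy class imbalance of AKI cohorts, multi-task outcome heads, and
inference-time adaptation — together with a seeded synthetic-cohort
simulator, so that every stage is testable without access-restricted
clinical databases.

## Labelling and cohort construction

`label_aki_kdigo()` evaluates the three KDIGO criteria on the hourly grid,
using observed cells only. The inequalities follow the printed thresholds:
creatinine criteria are inclusive (`>=`), the oliguria threshold is strict
(`<`), and "more than 6 h" means a contiguous run of at least 7 hourly
steps. The baseline for the relative criterion is the rolling minimum of
observed creatinine over the trailing 7 days, falling back to the earliest
observed value — the rolling minimum is the common operationalisation, and
it is deterministic. A flag switches between instantaneous per-step labels
(the default) and an absorbing first-onset convention; the definition
itself does not say whether post-onset steps stay labelled, so both are
supported.

`apply_cohort_filters()` retains adults (age ≥ 18) with no ESRD or dialysis
history, a usable baseline creatinine, at least 6 recorded steps, and at
least 12 consecutive recorded hours before onset. Retained records are
cropped to an observation window of at most 48 hourly steps, anchored at
first onset for positives and at the end of record for negatives.

## The synthetic cohort

`simulate_cohort()` generates the study conditions the model assumes.
Channels are Gaussian AR(1) processes around patient-level means (the
simplest process with tunable autocorrelation): creatinine (baseline
0.9 ± 0.15 mg/dL, marginal noise SD 0.05, lag-1 correlation 0.8),
weight-normalised urine rate (1.1 ± 0.25 mL/kg/h), systolic pressure, heart
rate, lactate, a binary vasopressor flag and a categorical unit type.
AKI-positive patients carry a planted deterioration: starting
`signal_lead_hours` (default 12) before onset, creatinine drifts upward by
about `0.45 × signal_effect` mg/dL and the urine rate declines into the
oliguric range. Labels are then produced by `label_aki_kdigo()` on the
generated trajectories themselves, so labels and physiology are consistent
by construction; prevalence is hit by rejection sampling on the labelled
outcome rather than by forcing labels. Missingness is applied per cell
(default 10%). Dialysis and recovery outcomes are drawn conditionally on
AKI with logits tilted by the same latent severity scalar that scales the
drift, giving the three task heads a learnable shared structure.

Defaults (prevalence 0.30, 24–48 hourly steps, lead 12 h, effect 1.0)
mirror the published ICU cohort descriptions this design emulates. What the
simulator does **not** emulate: pharmacology, organ-system coupling,
informative (care-driven) missingness, or the marginals of any real
dataset. Passing tests on this cohort therefore demonstrate that the
machinery can detect a planted temporal signal under realistic noise,
imbalance and missingness — not clinical performance on real EHR data.

`simulate_window_task()` is a second, deliberately minimal generator used
to stress the attention mechanism: pure-noise channels with a constant
offset planted in fixed mid-sequence windows, labels planted directly.

## Preprocessing

Gaps of at most `ffill_max_gap` steps (default 3 — a conservative clinical
carry-forward horizon) are filled forward, leading gaps backward; longer
gaps receive the patient-level median (mean optional), falling back to the
cohort median computed on the training split; categorical gaps receive a
sentinel code. The observed mask is never altered. Continuous channels are
z-scored with training-split statistics only. Batches are right-padded with
zeros and carry a step mask; padded positions contribute nothing to any
loss, and the padded-vs-per-sequence loss identity is tested to 1e-10.
Train-time augmentation adds Gaussian noise scaled to a fraction of each
channel's SD, rescales the time axis by a factor in (0.9, 1.1) with linear
resampling back onto the hourly grid (length-preserving, so the label grid
stays aligned), and masks non-essential channels — everything except the
channels the KDIGO rules read (creatinine, urine) — with a small
probability. Augmentation is training-only.

## The network

The encoder is a standard single-layer LSTM: input, forget and output gates
with a tanh candidate memory. On padded steps the previous state is carried
forward unchanged, which makes encoding invariant to masked padding. Two
prediction modes share the encoder:

* **sequence mode** — a per-step risk `sigmoid(w'h_t + b)` trained with the
  masked sequence cross-entropy (per-patient sum over steps, batch mean)
  plus a temporal smoothness penalty `gamma * sum_t (yhat_t - yhat_{t-1})^2`;
* **pooled mode** — attention scores `e_t = v' tanh(W_h h_t + b_h)`,
  softmax-normalised over real steps, pool `c = sum_t alpha_t h_t`, and one
  patient-level risk from `c`. The query `v` can be produced from the
  standardised static profile (`v = W_z z + b_z`), personalising the
  temporal focus.

Three affine-plus-sigmoid task heads (AKI, recovery, dialysis) sit on the
shared representation (`c` in pooled mode, the final real hidden state in
sequence mode) and are combined with fixed task weights or with trainable
uncertainty weighting `sum_k L_k/(2 sigma_k^2) + log sigma_k`.

### Initialisation

Weights are uniform on ±1/sqrt(fan-in). Two deliberate departures from
habit matter here because the optimiser is plain SGD at a small, fixed
schedule:

* **Forget-gate biases** are initialised to `log(u)` with `u` drawn
  half from 1–4 steps and half from 8–48 steps, so the cell states span
  retention horizons from an hour to the full observation window from the
  start (`sigmoid(log u) = u/(1+u)` retains information for roughly `u`
  steps). A constant bias of 1 gives every unit a ~4-step memory, which
  cannot represent a 12-hour creatinine trend until training has moved the
  biases — too slow under this schedule.
* **Output heads start at zero.** With a random head, whatever signal the
  random recurrent features carry projects through an arbitrary sign, so
  the untrained model can start far on the wrong side of chance and a slow
  optimiser cannot recover. A zero head makes the first gradient step
  choose the sign.

### Class imbalance

Per-step AKI labels are rare (about 1% of steps in the synthetic cohort).
The package combines the three standard levers: inverse-class-frequency
weights `w_c = N/(2 N_c)` (optionally updated each epoch from per-class
accuracy through `sigmoid(gamma (0.5 - p_c))`, combined multiplicatively
and renormalised to batch mean 1), focal loss (the printed positive-class
term plus a symmetric negative-class term, since the positive-only form
carries no gradient for negatives; class weights may modulate it, the
standard alpha-balanced variant), and SMOTE-based hybrid resampling.
Resampling interpolates flattened, imputed, normalised sequences between a
minority patient and one of its 5 nearest minority neighbours (interpolation
restricted to overlapping real steps; labels and outcomes copied from the
base patient, since interpolating binary labels is undefined), offset
exactly by random undersampling of the majority so the cohort size is
fixed. The bookkeeping (`resampling_plan()`) reports counts half-up
rounded, prevalence to 1 decimal and the majority:minority ratio to
2 decimals.

### The attention-entropy regulariser

The entropy of the attention weights can be pushed in either direction.
`entropy_sign = "diversity"` (default) adds `-beta * H(alpha)`, spreading
attention and preventing collapse onto a single step — the stated purpose
of the term; `"concentration"` adds `+beta * H(alpha)`, the literal penalty
on entropy. Both are exposed because the two readings circulate; nothing in
the package depends on which one is chosen. Near the uniform distribution
the entropy gradient vanishes (uniform is the entropy maximum), so the
term's visible effect grows only as the data term moves attention away from
uniform; the paired-seed test verifies the direction of the effect, which
is small but strictly consistent under the default optimiser.

## Training

Plain SGD, initial rate 0.001 decayed by a factor of 10 every 10 epochs,
mini-batches of 32, splits 80/10/10 by default and 70/15/15 for cohorts of
roughly a thousand patients. All randomness (split, initialisation, batch
order, resampling, augmentation) derives from the configured seed, and two
runs with the same configuration are bit-identical. The best
validation-AUC parameters are retained; a non-finite loss aborts with the
last good checkpoint.

The per-patient score of a sequence-mode model is its risk at the final
real step — the model's current estimate at the window anchor. A
maximum-over-time readout was rejected after it showed a systematic
sequence-length bias: negative patients keep longer windows than
onset-cropped positives, so the maximum over more noisy steps is inflated
for exactly the wrong class.

## Dynamic evaluation

At inference, `dynamic_evaluate()` processes a stream of patient windows:
predictions are emitted with the current parameters, then one SGD step is
taken on the window's observed labels and the parameters are pulled toward
the trained anchor. The elastic penalty `(lambda/2)||theta - theta*||^2`
is applied through its exact proximal map,
`theta <- theta* + (theta_sgd - theta*)/(1 + eta lambda)`, rather than as a
gradient term: the proximal form has the two limits the anchoring is meant
to guarantee — `eta = 0` reproduces static inference exactly and
`lambda = Inf` pins the parameters at the anchor — whereas a gradient step
on the penalty leaves the first update unanchored. Windows without labels
produce predictions only.

## Numerical choices

Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logarithms;
`0 log 0` is taken as 0 in the entropy; softmax subtracts the row maximum;
the L2 penalty covers weight matrices only (not biases or
log-uncertainties); zero-variance channels are left unscaled with a
warning; nearest-neighbour ties break by index; counts round half-up. All
gradients are analytic and checked against central finite differences at
relative error below 1e-4 on small random instances in the test suite.

## Experiment sizes

The shipped experiments are sized for a single CPU: the signal-recovery
experiment trains on 1,000 simulated patients for 15 epochs (about 15 s);
the attention ablation and entropy-direction suites train paired models
over 10 seeds on 600- and 120-patient window tasks; the dynamic-evaluation
experiment streams 200 shifted patients in windows of 8. These sizes were
chosen so the full suite runs in a few minutes while leaving the tested
effects clearly out of sampling noise.

## Known limitations

* The simulator's clean AR(1) physiology and ignorable missingness are far
  simpler than real EHR data; results on it bound nothing clinically.
* Sub-hourly events, irregular grids and model-based imputation (MICE,
  Gaussian processes) are out of scope; labels live on the hourly grid.
* KDIGO severity staging (stages 1–3) is not implemented — only the binary
  definition.
* The LSTM is single-layer and unidirectional; multi-head or
  transformer-style attention is deliberately not provided.
* Patient-level metrics assume the window-anchor convention described
  above; other deployments may want a different readout.
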