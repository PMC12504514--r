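Package: akinet
Title: Attention-Augmented Recurrent Models for Early Acute Kidney Injury Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hourly-resolution early-warning modelling of acute kidney
    injury (AKI) in intensive-care cohorts. Provides KDIGO rule-based per-step
    AKI labelling and cohort inclusion filters, a seeded synthetic ICU cohort
    simulator with a planted pre-onset physiological signal, imputation,
    normalisation, padding/masking and train-time augmentation for
    variable-length clinical time series, an LSTM sequence encoder with
    temporal attention (optionally personalised by a patient-context query)
    and multi-task outcome heads, composite training objectives (masked
    sequence cross-entropy, weighted and focal variants, temporal smoothness,
    attention-entropy regularisation, uncertainty-weighted multi-task loss),
    SMOTE-based hybrid resampling with exact class bookkeeping, plain-SGD
    training with a step learning-rate decay, rank-statistic evaluation
    metrics, component ablations and elastic-anchored dynamic evaluation at
    inference time. All numerics are base R with analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
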