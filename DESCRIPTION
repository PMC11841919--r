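Package: tsaforecast
Title: Two-Stage-Attention LSTM Forecasting of Sparse Annual Incidence Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasting stack for sparse annual epidemiological time series such as
    age-standardized cancer incidence rates. Annual observations are augmented to a
    monthly grid by linear, quadratic or cubic spline interpolation with a
    deliberate-deletion holdout protocol for method selection; forecasts come from a
    dual-stage-attention LSTM (input attention over exogenous driving series, temporal
    attention over encoder states) trained with minibatch Adam and early stopping, a
    Holt double-exponential-smoothing baseline, and a zoo of nine recurrent baseline
    architectures under a common train/predict contract. Includes forecast-accuracy
    metrics (RMSE, MAE, MASE, MAPE, AIC), qualitative trend descriptors, growth-rate
    projection tables, seeded synthetic-data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
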