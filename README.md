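# tsaforecast

Forecasting sparse annual epidemiological series — such as age-standardized
cancer-incidence rates reported once per year — with a two-stage-attention
LSTM, after spline-based augmentation of the annual series to a monthly grid.
The package is aimed at epidemiological modellers who need long-horizon trend
projections from short annual series plus a small panel of risk-factor
driving series (e.g. tobacco smoking, alcohol consumption, physical
inactivity, obesity).

## What it implements

**Spline augmentation with holdout method selection.** An annual series
`(year, y)` is interpolated by one of three families — piecewise-linear
chords (C0), piecewise quadratics built from the derivative recursion
`D_i = 2 (y_i − y_{i−1})/h_i − D_{i−1}` (C1), or the natural cubic spline
from a tridiagonal solve (C2) — and evaluated on a consecutive monthly grid.
Months coinciding with an annual observation reproduce it exactly
(`anchor`); the method is chosen by a deliberate-deletion protocol: keep a
subset of years, predict the held-out years with each family, select the
argmin-MAE family.

**TSA-LSTM.** A windowed NARX model: for each time `t` the model sees the
length-τ windows of `n` driving series and the τ−1 past target values, and
predicts `y_t`. Stage one (input attention) reweights the driving series at
every encoder step,

    e_t^a = v_e' tanh(W_e [h_{t−1}; c_{t−1}] + U_e x^a),   α_t = softmax_a(e_t^a),

so the LSTM encoder consumes `x̂_t = α_t ⊙ x_t`. Stage two (temporal
attention) scores all τ encoder states from the decoder state,
`β_t = softmax_i( v_d' tanh(W_d [d_{t−1}; c_{t−1}'] + U_d h_i) )`, forms the
context vector `ĉ_t = Σ_i β_t^i h_i`, fuses it with the previous target
(`ỹ_{t−1} = w̃' [y_{t−1}; ĉ_{t−1}] + b̃`) as the decoder LSTM input, and reads
out `ŷ = W [d_τ; ĉ_τ] + b`. Training is minibatch Adam on MSE with dropout
and early stopping; the recurrent cells, attention blocks and the
reverse-mode autodiff behind them are implemented in the package (pure R
matrix operations) and verified against finite differences.

**Baselines and evaluation.** A Holt double-exponential-smoothing baseline
(level + trend, additive or multiplicative, no seasonality; coefficients
fixed or grid-searched), nine recurrent baselines (GRU / BiGRU / LSTM /
BiLSTM, their seq2seq variants, and seq2seq LSTM + input attention) under
the same train/predict contract, a repeated-run benchmark harness, the
forecast-accuracy bundle (RMSE, MAE, MAPE, MASE, AIC, accuracy = 100 −
MAPE), qualitative trend-shape descriptors, and growth-rate projection
tables. Seeded synthetic generators emulate the annual incidence layout
(~32 years near 137 per 100,000) and a monthly driver/target panel in which
exactly one of four drivers is causal.

## Worked example

```r
library(tsaforecast)

# synthetic study conditions: 32 annual observations 1990-2021
annual <- gen_annual(synth_spec(seed = 1))

# pick the interpolation method by deliberate deletion, then augment
holdout_select(annual)
#> <holdout_report> 12 kept / 20 held years; winner: linear
#>     method      mae     rmse
#>     linear 1.331528 1.743175
#>  quadratic 1.722620 2.129876
#>      cubic 1.381107 1.739465
monthly <- expand_monthly(annual, method = holdout_select(annual)$winner)
monthly
#> <monthly_series> 420 months (1990-01 to 2024-12)
#>        anchor interpolated extrapolated     forecast
#>            32          341           47            0
```

(On this noisy draw the linear interpolant wins the holdout; on smooth
curved series — and on the deterministic acceptance check — the cubic
spline wins.)

The 32 annual entries become 420 monthly entries; every anchor month equals
its annual value exactly, and months beyond the last anchor are terminal-
piece extrapolations (replaceable by model forecasts downstream).

```r
# Holt baseline on the annual series
des <- fit_des(annual$values, mode = "multiplicative")
des_report(des)$metrics$mape     # in-sample MAPE ~0.94 %

# TSA-LSTM on the monthly driver/target panel
panel <- gen_drivers_and_target(synth_spec(seed = 1))
ds    <- make_windows(panel$drivers, panel$target, tau = 12)
split <- split_windows(ds, test = 36, val = 36)
cfg   <- tsa_config(n = 4, tau = 12, s = 32, p = 32, lr = 0.01,
                    max_epochs = 200, patience = 40, seed = 1)
fit   <- train_model(build_tsa(cfg), ds, split)
pred  <- predict(fit, ds, samples = split$test)
compute_metrics(ds$labels[split$test], pred,
                training = ds$labels[split$train])$mape
#> [1] 3.865965        # vs 5.63 for the one-step naive forecaster
mean(attention_trace(fit, ds, split$train)$alphas[1, , ])
#> [1] 0.2626035       # causal driver weighted above the uniform 0.25
```

The test-set MAPE of ~3.9 % beats the one-step naive baseline (~5.6 %), and
the input-attention weight on the causal driver exceeds the uniform weight
1/4 — the model identifies which risk-factor series drives the target.

A command-line front end wrapping the same functions ships in
`inst/cli/tsaforecast.R`:

```sh
Rscript inst/cli/tsaforecast.R simulate --seed 7 --out fixture
Rscript inst/cli/tsaforecast.R augment --input fixture/annual.csv \
    --method auto --out monthly.csv
Rscript inst/cli/tsaforecast.R fit-des --input fixture/annual.csv --out des.json
```

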