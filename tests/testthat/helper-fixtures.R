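# Shared fixtures for the test suite; everything is generated in code.

# small annual series with a smooth rising trend
fix_annual <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  years <- 2000L + seq_len(n) - 1L
  annual_series(years, 100 + 0.7 * seq_len(n) + rnorm(n, 0, 0.5))
}

# 32-anchor series on the 1990-2021 layout, values from a cubic polynomial
fix_cubic_series <- function() {
  yrs <- 1990:2021
  k <- yrs - 1990
  annual_series(yrs, 120 + 0.6 * k + 0.015 * k^2 + 0.0025 * k^3)
}

# small windowed dataset + untrained TSA handle with seeded parameters
fix_tsa <- function(n = 3L, tau = 4L, s = 3L, p = 3L, T_ = 30L, seed = 5L) {
  set.seed(seed)
  drivers <- matrix(rnorm(T_ * n), T_, n)
  target <- 10 + 0.1 * seq_len(T_) + drivers[, 1] + rnorm(T_, 0, 0.1)
  ds <- make_windows(drivers, target, tau)
  cfg <- tsa_config(n = n, tau = tau, s = s, p = p, seed = seed, dropout = 0)
  h <- build_tsa(cfg)
  set.seed(seed + 1L)
  h$params <- h$init()
  list(ds = ds, handle = h, cfg = cfg)
}

# per-sample view of one dataset entry
fix_sample <- function(ds, i) {
  list(
    windows = matrix(ds$windows[, , i], nrow = ds$n),
    past = ds$past[, i]
  )
}
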