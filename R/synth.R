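#' Specification for the synthetic incidence generators
#'
#' Parameters of the seeded generators that emulate the layout and scale of
#' national cancer-incidence extracts: ~32 annual observations of an
#' age-standardized rate near 137 per 100,000 with a mild rising trend, and
#' (for the monthly generator) a small panel of autocorrelated risk-factor
#' driving series of which one is causally coupled to the target.
#'
#' @param n_years Number of annual observations (default 32).
#' @param start_year First calendar year (default 1990).
#' @param base Level in the first year (default 136.95 per 100,000).
#' @param trend Linear trend per year (default 0.8).
#' @param curvature Quadratic coefficient per year squared (default 0.02).
#' @param noise_sd Gaussian noise standard deviation on annual values
#'   (default 1.5).
#' @param n_months Length of the monthly generator's output (default 420).
#' @param month_base,month_trend Level and per-month linear trend of the
#'   monthly target (defaults 110 and 0.08).
#' @param seasonal_amp Amplitude of the 12-month seasonal term (default 4).
#' @param month_noise_sd Gaussian noise on the monthly target (default 2;
#'   set 0 for the noiseless variant).
#' @param n_drivers Number of driving series (default 4, mirroring tobacco
#'   smoking, alcohol consumption, physical inactivity, obesity).
#' @param causal Index of the causally informative driver (default 1).
#' @param coupling Coefficient linking the causal driver to the target
#'   (default 8).
#' @param lag Lag, in months, of the causal influence (default 0).
#' @param ar_coef AR(1) coefficient of every driver (default 0.8).
#' @param seed Integer seed; fully determines all generator output.
#' @return A list of class \code{synth_spec}.
#' @export
synth_spec <- function(n_years = 32L, start_year = 1990L, base = 136.95,
                       trend = 0.8, curvature = 0.02, noise_sd = 1.5,
                       n_months = 420L, month_base = 110, month_trend = 0.08,
                       seasonal_amp = 4, month_noise_sd = 2,
                       n_drivers = 4L, causal = 1L, coupling = 8, lag = 0L,
                       ar_coef = 0.8, seed = 1L) {
  spec <- list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    base = base, trend = trend, curvature = curvature, noise_sd = noise_sd,
    n_months = as.integer(n_months), month_base = month_base,
    month_trend = month_trend, seasonal_amp = seasonal_amp,
    month_noise_sd = month_noise_sd, n_drivers = as.integer(n_drivers),
    causal = as.integer(causal), coupling = coupling, lag = as.integer(lag),
    ar_coef = ar_coef, seed = as.integer(seed)
  )
  stopifnot(spec$n_years >= 4L, spec$n_drivers >= 1L,
            spec$causal >= 1L, spec$causal <= spec$n_drivers,
            spec$lag >= 0L, spec$lag < spec$n_months)
  class(spec) <- "synth_spec"
  spec
}

#' Generate a synthetic annual incidence series
#'
#' \eqn{y_k = base + trend \cdot k + curvature \cdot k^2 + N(0, sd)} over
#' \code{n_years} consecutive years; deterministic per seed.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return An \code{\link{annual_series}}.
#' @examples
#' gen_annual(synth_spec(seed = 7))
#' @export
gen_annual <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    k <- 0:(spec$n_years - 1L)
    vals <- spec$base + spec$trend * k + spec$curvature * k^2 +
      stats::rnorm(spec$n_years, 0, spec$noise_sd)
    if (any(vals <= 0)) {
      stop("generator parameters produce non-positive incidence values", call. = FALSE)
    }
    annual_series(spec$start_year + k, vals, label = "synthetic incidence")
  })
}

#' Generate monthly driving series and a coupled target
#'
#' Drivers are independent AR(1) paths (coefficient \code{ar_coef}, unit
#' innovations). The target is
#' \deqn{y_t = base + trend \cdot t + A \sin(2\pi t / 12)
#'       + coupling \cdot x^{(causal)}_{t - lag} + N(0, sd),}
#' so exactly one driver is causally informative while the remaining ones
#' are decoys with the same marginal structure. Deterministic per seed.
#'
#' @param spec A \code{\link{synth_spec}}.
#' @return List with \code{drivers} (\code{n_months x n_drivers} matrix) and
#'   \code{target} (length \code{n_months}).
#' @export
gen_drivers_and_target <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed + 1L, {
    T_ <- spec$n_months
    n <- spec$n_drivers
    drivers <- matrix(0, T_, n)
    sd0 <- 1 / sqrt(1 - spec$ar_coef^2)  # stationary start
    for (j in seq_len(n)) {
      x <- numeric(T_)
      x[1] <- stats::rnorm(1, 0, sd0)
      eps <- stats::rnorm(T_ - 1L)
      for (t in 2:T_) x[t] <- spec$ar_coef * x[t - 1L] + eps[t - 1L]
      drivers[, j] <- x
    }
    colnames(drivers) <- paste0("driver_", seq_len(n))
    t_ <- seq_len(T_)
    causal_part <- numeric(T_)
    src <- t_ - spec$lag
    ok <- src >= 1L
    causal_part[ok] <- drivers[src[ok], spec$causal]
    target <- spec$month_base + spec$month_trend * t_ +
      spec$seasonal_amp * sin(2 * pi * t_ / 12) +
      spec$coupling * causal_part +
      stats::rnorm(T_, 0, spec$month_noise_sd)
    list(drivers = drivers, target = target)
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Produces a directory holding an annual incidence CSV (readable by
#' \code{\link{read_annual_csv}}), a monthly driver/target CSV, and a JSON
#' manifest echoing the generating spec. Byte-identical for identical
#' seeds.
#'
#' @param dir Output directory (created if needed).
#' @param spec A \code{\link{synth_spec}}.
#' @return Invisibly, the paths of the three files written.
#' @export
gen_bundle <- function(dir, spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  annual_path <- file.path(dir, "annual.csv")
  drivers_path <- file.path(dir, "drivers.csv")
  manifest_path <- file.path(dir, "manifest.json")
  write_annual_csv(gen_annual(spec), annual_path)
  dt <- gen_drivers_and_target(spec)
  df <- data.frame(t = seq_len(spec$n_months))
  for (j in seq_len(spec$n_drivers)) df[[colnames(dt$drivers)[j]]] <- fmt_full(dt$drivers[, j])
  df$target <- fmt_full(dt$target)
  utils::write.csv(df, drivers_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(generator = "tsaforecast::gen_bundle", spec = unclass(spec)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(annual = annual_path, drivers = drivers_path, manifest = manifest_path))
}
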