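#' Fit a Holt double-exponential-smoothing model
#'
#' Level-plus-trend exponential smoothing with no seasonal component
#' (gamma fixed at 0). Additive recursions:
#' \deqn{\ell_t = \alpha y_t + (1-\alpha)(\ell_{t-1} + b_{t-1}), \quad
#'       b_t = \beta(\ell_t - \ell_{t-1}) + (1-\beta) b_{t-1}}
#' The multiplicative variant replaces sums with products and differences
#' with ratios (\eqn{\ell_t = \alpha y_t + (1-\alpha)\ell_{t-1} b_{t-1}},
#' \eqn{b_t = \beta\,\ell_t/\ell_{t-1} + (1-\beta) b_{t-1}}) and requires
#' strictly positive data. States are initialized from the first two
#' observations: \eqn{\ell_1 = y_1} and \eqn{b_1 = y_2 - y_1} (additive) or
#' \eqn{y_2 / y_1} (multiplicative).
#'
#' When \code{alpha}/\code{beta} are omitted they are chosen by an exhaustive
#' deterministic grid search over \eqn{\{0.01, \dots, 0.99\}^2} (step 0.01)
#' minimizing in-sample one-step RMSE.
#'
#' @param y Numeric series, length >= 3.
#' @param mode \code{"additive"} or \code{"multiplicative"}.
#' @param alpha,beta Optional fixed smoothing coefficients in (0,1); both
#'   must be supplied together.
#' @return An object of class \code{des_model}: coefficients, final state
#'   \code{(level, trend)}, in-sample one-step \code{fitted} values (aligned
#'   with \code{y}; first entry \code{NA}), and the data.
#' @examples
#' y <- 2 + 3 * (1:20)
#' m <- fit_des(y, mode = "additive", alpha = 0.4, beta = 0.3)
#' des_forecast(m, 3)  # exact affine continuation
#' @export
fit_des <- function(y, mode = c("additive", "multiplicative"),
                    alpha = NULL, beta = NULL) {
  mode <- match.arg(mode)
  y <- as.numeric(y)
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(y))) stop("series must be finite", call. = FALSE)
  if (mode == "multiplicative" && any(y <= 0)) {
    stop("multiplicative mode requires strictly positive data", call. = FALSE)
  }
  if (xor(is.null(alpha), is.null(beta))) {
    stop("supply both `alpha` and `beta`, or neither", call. = FALSE)
  }
  optimized <- is.null(alpha)
  if (optimized) {
    ab <- des_grid_search(y, mode)
    alpha <- ab[1]; beta <- ab[2]
  } else {
    if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1) {
      stop("alpha and beta must lie in (0, 1)", call. = FALSE)
    }
  }
  run <- holt_recursion(y, alpha, beta, mode)
  structure(
    list(
      alpha = alpha, beta = beta, gamma = 0, mode = mode,
      level = run$level, trend = run$trend, fitted = run$fitted,
      y = y, optimized = optimized
    ),
    class = "des_model"
  )
}

# One pass of the Holt recursions. Returns final state and the one-step
# in-sample forecasts (fitted[t] predicts y[t] from the state at t-1).
holt_recursion <- function(y, alpha, beta, mode) {
  n <- length(y)
  fitted <- rep(NA_real_, n)
  if (mode == "additive") {
    l <- y[1]; b <- y[2] - y[1]
    for (t in 2:n) {
      fitted[t] <- l + b
      l_new <- alpha * y[t] + (1 - alpha) * (l + b)
      b <- beta * (l_new - l) + (1 - beta) * b
      l <- l_new
    }
  } else {
    l <- y[1]; b <- y[2] / y[1]
    for (t in 2:n) {
      fitted[t] <- l * b
      l_new <- alpha * y[t] + (1 - alpha) * (l * b)
      b <- beta * (l_new / l) + (1 - beta) * b
      l <- l_new
    }
  }
  list(level = l, trend = b, fitted = fitted)
}

# Exhaustive (alpha, beta) scan on the 0.01-step grid, vectorized across the
# grid by running the recursion once with coefficient vectors.
des_grid_search <- function(y, mode) {
  g <- seq(0.01, 0.99, by = 0.01)
  alpha <- rep(g, times = length(g))
  beta <- rep(g, each = length(g))
  n <- length(y)
  sse <- numeric(length(alpha))
  if (mode == "additive") {
    l <- rep(y[1], length(alpha)); b <- rep(y[2] - y[1], length(alpha))
    for (t in 2:n) {
      pred <- l + b
      sse <- sse + (y[t] - pred)^2
      l_new <- alpha * y[t] + (1 - alpha) * pred
      b <- beta * (l_new - l) + (1 - beta) * b
      l <- l_new
    }
  } else {
    l <- rep(y[1], length(alpha)); b <- rep(y[2] / y[1], length(alpha))
    for (t in 2:n) {
      pred <- l * b
      sse <- sse + (y[t] - pred)^2
      l_new <- alpha * y[t] + (1 - alpha) * pred
      b <- beta * (l_new / l) + (1 - beta) * b
      l <- l_new
    }
  }
  k <- which.min(sse)  # first minimum: deterministic tie-break
  c(alpha[k], beta[k])
}

#' @export
print.des_model <- function(x, ...) {
  cat(sprintf(
    "<des_model> %s Holt: alpha = %.3f, beta = %.3f, gamma = %.3f%s\n",
    x$mode, x$alpha, x$beta, x$gamma,
    if (x$optimized) " (grid-searched)" else ""
  ))
  cat(sprintf("  final state: level = %.6g, trend = %.6g\n", x$level, x$trend))
  invisible(x)
}

#' Forecast from a fitted Holt model
#'
#' Additive forecasts are affine in the horizon,
#' \eqn{\hat y_{t+h} = \ell_t + h b_t}; multiplicative forecasts are
#' geometric, \eqn{\hat y_{t+h} = \ell_t b_t^h}.
#'
#' @param model A \code{des_model}.
#' @param h Forecast horizon (number of steps), >= 1.
#' @return Numeric vector of \code{h} forecasts.
#' @export
des_forecast <- function(model, h) {
  stopifnot(inherits(model, "des_model"))
  h <- as.integer(h)
  if (h < 1L) stop("`h` must be >= 1", call. = FALSE)
  steps <- seq_len(h)
  if (model$mode == "additive") {
    model$level + steps * model$trend
  } else {
    model$level * model$trend^steps
  }
}

#' @export
predict.des_model <- function(object, h = 36L, ...) des_forecast(object, h)

#' Quality report for a Holt fit
#'
#' Mirrors the usual smoothing-forecast summary: forecast horizon, in-sample
#' quality metrics (via \code{\link{compute_metrics}} on the one-step fitted
#' values, charging 4 free parameters in the AIC: alpha, beta and the two
#' initial states), the smoothing coefficients (gamma always 0), and the
#' point forecasts.
#'
#' @param model A \code{des_model}.
#' @param horizon Forecast length in steps (default 36, i.e. a 3-year
#'   monthly horizon).
#' @return A list of class \code{des_report} with \code{metrics},
#'   \code{forecast}, \code{coefficients}, \code{horizon}, \code{mode}.
#' @export
des_report <- function(model, horizon = 36L) {
  stopifnot(inherits(model, "des_model"))
  ok <- !is.na(model$fitted)
  metrics <- compute_metrics(
    actual = model$y[ok], predicted = model$fitted[ok],
    training = model$y, n_par = 4L
  )
  structure(
    list(
      horizon = as.integer(horizon),
      mode = model$mode,
      coefficients = c(alpha = model$alpha, beta = model$beta, gamma = 0),
      metrics = metrics,
      forecast = des_forecast(model, horizon)
    ),
    class = "des_report"
  )
}

#' @export
print.des_report <- function(x, ...) {
  cat(sprintf(
    "<des_report> %s Holt, forecast length %d steps\n", x$mode, x$horizon
  ))
  cat(sprintf(
    "  coefficients: alpha = %.3f, beta = %.3f, gamma = %.3f\n",
    x$coefficients["alpha"], x$coefficients["beta"], x$coefficients["gamma"]
  ))
  print(x$metrics)
  invisible(x)
}
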