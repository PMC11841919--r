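#' Annual incidence series
#'
#' Container for an ordered annual time series of a non-negative incidence
#' measure (typically an age-standardized rate per 100,000), optionally
#' carrying exogenous driving series (risk factors) observed on the same
#' years.
#'
#' @param years Integer vector of calendar years, strictly increasing.
#' @param values Numeric vector of non-negative, finite observations, one per
#'   year.
#' @param label Character scalar naming the measure.
#' @param factors Optional numeric matrix (or data frame) of driving series,
#'   one row per year, named columns.
#'
#' @return An object of class \code{annual_series}: a list with elements
#'   \code{years}, \code{values}, \code{label} and (possibly \code{NULL})
#'   \code{factors}.
#' @examples
#' s <- annual_series(1990:1995, c(100, 102, 104, 103, 107, 110))
#' s
#' @export
annual_series <- function(years, values, label = "incidence", factors = NULL) {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have equal length", call. = FALSE)
  }
  if (anyNA(years) || any(diff(years) <= 0)) {
    stop("`years` must be strictly increasing with no duplicates", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and non-negative", call. = FALSE)
  }
  if (!is.null(factors)) {
    factors <- as.matrix(factors)
    storage.mode(factors) <- "double"
    if (nrow(factors) != length(years)) {
      stop("`factors` must have one row per year", call. = FALSE)
    }
    if (is.null(colnames(factors))) {
      colnames(factors) <- paste0("factor_", seq_len(ncol(factors)))
    }
  }
  structure(
    list(years = years, values = values, label = label, factors = factors),
    class = "annual_series"
  )
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf(
    "<annual_series> %s: %d years (%d-%d)%s\n",
    x$label, length(x$years), min(x$years), max(x$years),
    if (is.null(x$factors)) "" else sprintf(", %d driving series", ncol(x$factors))
  ))
  print(utils::head(data.frame(year = x$years, value = x$values), 6))
  if (length(x$years) > 6) cat(sprintf("... %d more rows\n", length(x$years) - 6))
  invisible(x)
}

#' @export
length.annual_series <- function(x) length(x$years)

#' Monthly series with provenance tags
#'
#' A gap-free monthly timeline. Every entry carries a provenance tag:
#' \code{anchor} entries coincide with an original annual observation and
#' reproduce it exactly, \code{interpolated} entries lie inside the anchored
#' span, \code{extrapolated} entries lie beyond it, and \code{forecast}
#' entries come from a downstream forecasting model.
#'
#' @param year,month Integer vectors; months in 1..12, jointly consecutive
#'   (every entry exactly one month after the previous).
#' @param value Numeric vector.
#' @param source Character vector of per-entry tags.
#' @return An object of class \code{monthly_series}.
#' @export
monthly_series <- function(year, month, value, source) {
  year <- as.integer(year); month <- as.integer(month)
  value <- as.numeric(value); source <- as.character(source)
  n <- length(year)
  if (length(month) != n || length(value) != n || length(source) != n) {
    stop("all fields must have equal length", call. = FALSE)
  }
  if (any(month < 1L) || any(month > 12L)) {
    stop("months must lie in 1..12", call. = FALSE)
  }
  idx <- year * 12L + (month - 1L)
  if (n > 1L && any(diff(idx) != 1L)) {
    stop("monthly index must be consecutive with no gaps", call. = FALSE)
  }
  bad <- setdiff(unique(source), c("anchor", "interpolated", "extrapolated", "forecast"))
  if (length(bad)) {
    stop("unknown source tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(year = year, month = month, value = value, source = source),
    class = "monthly_series"
  )
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$value)
  cat(sprintf(
    "<monthly_series> %d months (%d-%02d to %d-%02d)\n",
    n, x$year[1], x$month[1], x$year[n], x$month[n]
  ))
  print(table(factor(x$source,
    levels = c("anchor", "interpolated", "extrapolated", "forecast"))))
  invisible(x)
}

#' @export
length.monthly_series <- function(x) length(x$value)

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(year = x$year, month = x$month, value = x$value, source = x$source)
}

check_numeric_pair <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("inputs must be non-empty", call. = FALSE)
  if (any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop("inputs must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Forecast errors
#'
#' Elementwise forecast error \eqn{e_{T+h} = y_{T+h} - \hat y_{T+h|T}}: the
#' difference between an observed value and its forecast.
#'
#' @param actual,predicted Equal-length finite numeric vectors.
#' @return Numeric vector of the same length.
#' @examples
#' forecast_errors(c(3, 5), c(2, 5))
#' @export
forecast_errors <- function(actual, predicted) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  check_numeric_pair(actual, predicted)
  actual - predicted
}

#' Forecast accuracy metrics
#'
#' Computes the metric bundle used throughout the package for model
#' comparison: RMSE, MAE, MAPE (percent), MASE (scaled by the in-sample
#' one-step naive MAE of \code{training}), an AIC under the sum-of-squares
#' convention \eqn{n \log(SSE/n) + 2k}, plus \code{accuracy = 100 - MAPE}
#' and \code{error_pct = MAPE}.
#'
#' @param actual,predicted Equal-length numeric vectors of observed and
#'   forecast values; \code{actual} must be nonzero everywhere for MAPE.
#' @param training Numeric vector (length >= 2) of the training series used
#'   to scale MASE.
#' @param n_par Number of free parameters charged in the AIC penalty
#'   (default 2; a Holt fit uses 4: two smoothing coefficients plus two
#'   initial states).
#' @return An object of class \code{metric_set}: a named list with elements
#'   \code{rmse}, \code{mae}, \code{mape}, \code{mase}, \code{aic},
#'   \code{accuracy}, \code{error_pct}.
#' @examples
#' y <- c(10, 11, 13, 14, 16)
#' compute_metrics(y[-1], y[-5], training = y)  # one-step naive: MASE = 1
#' @export
compute_metrics <- function(actual, predicted, training, n_par = 2L) {
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  training <- as.numeric(training)
  check_numeric_pair(actual, predicted)
  if (length(training) < 2L) {
    stop("`training` must contain at least 2 observations", call. = FALSE)
  }
  if (any(actual == 0)) {
    stop("MAPE undefined: `actual` contains zero values", call. = FALSE)
  }
  e <- actual - predicted
  n <- length(e)
  rmse <- sqrt(mean(e^2))
  mae <- mean(abs(e))
  mape <- 100 * mean(abs(e / actual))
  scale <- mean(abs(diff(training)))
  mase <- if (scale == 0) NA_real_ else mae / scale
  sse <- sum(e^2)
  aic <- n * log(sse / n) + 2 * n_par
  structure(
    list(
      rmse = rmse, mae = mae, mape = mape, mase = mase, aic = aic,
      accuracy = 100 - mape, error_pct = mape
    ),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  for (k in names(x)) cat(sprintf("  %-9s %.6g\n", k, x[[k]]))
  invisible(x)
}

#' One-step naive forecast
#'
#' In-sample one-step naive predictions: each value forecast by its
#' predecessor. The first observation has no forecast and is dropped, so the
#' returned \code{actual} aligns with \code{predicted}.
#'
#' @param y Numeric vector, length >= 2.
#' @return List with \code{actual} (\code{y[-1]}) and \code{predicted}
#'   (\code{y} without its last element).
#' @export
naive_one_step <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  list(actual = y[-1L], predicted = y[-length(y)])
}

# full-precision numeric rendering for CSV round trips
fmt_full <- function(x) sprintf("%.17g", x)

#' Read an annual series from CSV
#'
#' Column contract: header \code{year,value[,factor_1,...,factor_k]}; one row
#' per year, years sorted strictly increasing. Any columns beyond the first
#' two are read as driving series.
#'
#' @param path Path to a CSV file.
#' @param label Label for the resulting series.
#' @return An \code{\link{annual_series}}.
#' @export
read_annual_csv <- function(path, label = "incidence") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("year", "value") %in% names(df))) {
    stop("annual CSV must have columns `year` and `value`: ", path, call. = FALSE)
  }
  for (col in names(df)) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric cell in column `%s`, row %d", col, bad), call. = FALSE)
    }
  }
  factors <- NULL
  extra <- setdiff(names(df), c("year", "value"))
  if (length(extra)) factors <- as.matrix(df[extra])
  annual_series(df$year, df$value, label = label, factors = factors)
}

#' Write an annual series to CSV
#'
#' @param series An \code{\link{annual_series}}.
#' @param path Output path.
#' @export
write_annual_csv <- function(series, path) {
  stopifnot(inherits(series, "annual_series"))
  df <- data.frame(year = series$years, value = fmt_full(series$values))
  if (!is.null(series$factors)) {
    for (nm in colnames(series$factors)) df[[nm]] <- fmt_full(series$factors[, nm])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a monthly series to CSV
#'
#' Values are rendered at full double precision so that
#' \code{read_monthly_csv(write_monthly_csv(s))} reproduces \code{s}
#' bit-exactly.
#'
#' @param series A \code{\link{monthly_series}}.
#' @param path Output path.
#' @export
write_monthly_csv <- function(series, path) {
  stopifnot(inherits(series, "monthly_series"))
  df <- data.frame(
    year = series$year, month = series$month,
    value = fmt_full(series$value), source = series$source
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly series from CSV
#'
#' Column contract: \code{year,month,value,source} with the constraints of
#' \code{\link{monthly_series}}.
#'
#' @param path Path to a CSV file.
#' @return A \code{\link{monthly_series}}.
#' @export
read_monthly_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("year", "month", "value", "source")
  if (!all(need %in% names(df))) {
    stop("monthly CSV must have columns year,month,value,source: ", path, call. = FALSE)
  }
  monthly_series(df$year, df$month, df$value, df$source)
}
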