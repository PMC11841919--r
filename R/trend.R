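# Qualitative forecast descriptors (shape "filtering" and distance-to-truth
# classes) and the growth-rate projection table.

# a path is undulating iff its first differences change sign at least
# `min_sign_changes` times; linear iff the first differences are constant
path_shape <- function(path, min_sign_changes = 2L, linear_tol = 1e-9) {
  d <- diff(path)
  scale <- max(abs(d), 1e-12)
  if (max(d) - min(d) <= linear_tol * scale) return("linear")
  sgn <- sign(d[d != 0])
  changes <- if (length(sgn) > 1L) sum(diff(sgn) != 0) else 0L
  if (changes >= min_sign_changes) "undulating" else "non_undulating"
}

#' Classify the joint shape of two forecast paths
#'
#' Each path is classed as linear (numerically constant first differences),
#' undulating (first differences change sign at least
#' \code{min_sign_changes} times) or non-undulating. Two training instances
#' whose paths share a class give a \code{full_*} label; differing classes
#' give \code{partial_*}; two linear paths give \code{"linear"}.
#'
#' @param instance_a,instance_b Numeric forecast paths, length >= 4.
#' @param min_sign_changes Sign-change threshold defining undulation.
#' @return One of \code{"linear"}, \code{"full_undulating"},
#'   \code{"partial_undulating"}, \code{"full_non_undulating"},
#'   \code{"partial_non_undulating"}.
#' @export
classify_filtering <- function(instance_a, instance_b, min_sign_changes = 2L) {
  instance_a <- as.numeric(instance_a); instance_b <- as.numeric(instance_b)
  if (length(instance_a) < 4L || length(instance_b) < 4L) {
    stop("forecast paths must have length >= 4", call. = FALSE)
  }
  sa <- path_shape(instance_a, min_sign_changes)
  sb <- path_shape(instance_b, min_sign_changes)
  if (sa == "linear" && sb == "linear") return("linear")
  if (sa == sb) return(paste0("full_", sa))
  # mixed classes: report partial on the undulation axis; a linear path
  # counts as non-undulating for the pairing
  und <- c(sa, sb) == "undulating"
  if (any(und)) "partial_undulating" else "partial_non_undulating"
}

#' Classify distance of two forecast instances to the true trend
#'
#' An instance qualifies as close when its mean absolute deviation from the
#' truth is at most \code{theta} times the truth scale (mean absolute truth
#' value). Both close: \code{"full"}; exactly one: \code{"partial"};
#' neither: \code{"partial"} with attribute \code{neither = TRUE}.
#'
#' @param instance_a,instance_b Numeric forecast paths.
#' @param truth Numeric true path of the same length.
#' @param theta Relative tolerance (default 0.1).
#' @return \code{"full"} or \code{"partial"}.
#' @export
classify_distance <- function(instance_a, instance_b, truth, theta = 0.1) {
  instance_a <- as.numeric(instance_a); instance_b <- as.numeric(instance_b)
  truth <- as.numeric(truth)
  if (length(instance_a) != length(truth) || length(instance_b) != length(truth)) {
    stop("paths and truth must have equal length", call. = FALSE)
  }
  tol <- theta * mean(abs(truth))
  close_a <- mean(abs(instance_a - truth)) <= tol
  close_b <- mean(abs(instance_b - truth)) <= tol
  if (close_a && close_b) return("full")
  out <- "partial"
  if (!close_a && !close_b) attr(out, "neither") <- TRUE
  out
}

#' Growth-rate projection table
#'
#' Expresses annual predictions as integer percent increases over a baseline
#' year: \eqn{\mathrm{round}(100 (\hat y_y - y_{base}) / y_{base})}.
#'
#' @param annual_predictions Named numeric vector (names = years) or a
#'   data frame with columns \code{year} and \code{value}.
#' @param baseline_year Reference year; must be present with a nonzero
#'   value. Defaults to the earliest year supplied.
#' @return A data frame of class \code{growth_table} with columns
#'   \code{year}, \code{prediction}, \code{percent_increase}.
#' @examples
#' growth_rates(c(`2021` = 100, `2022` = 110, `2023` = 122), 2021)
#' @export
growth_rates <- function(annual_predictions, baseline_year = NULL) {
  if (is.data.frame(annual_predictions)) {
    years <- as.integer(annual_predictions$year)
    vals <- as.numeric(annual_predictions$value)
  } else {
    years <- as.integer(names(annual_predictions))
    vals <- as.numeric(annual_predictions)
  }
  if (anyNA(years)) stop("years must be supplied as names or a `year` column", call. = FALSE)
  if (is.null(baseline_year)) baseline_year <- min(years)
  k <- match(as.integer(baseline_year), years)
  if (is.na(k)) stop("baseline year not present in predictions", call. = FALSE)
  base <- vals[k]
  if (base == 0) stop("baseline value must be nonzero", call. = FALSE)
  out <- data.frame(
    year = years,
    prediction = vals,
    percent_increase = as.integer(round(100 * (vals - base) / base))
  )
  attr(out, "baseline_year") <- as.integer(baseline_year)
  class(out) <- c("growth_table", "data.frame")
  out
}

#' Aggregate a monthly forecast path to annual values
#'
#' Annual value = the December entry of each complete year (the
#' \code{"december"} rule) or the mean over the year's months
#' (\code{"mean"}).
#'
#' @param series A \code{\link{monthly_series}}.
#' @param rule \code{"december"} (default) or \code{"mean"}.
#' @return Named numeric vector of annual values (names = years).
#' @export
annualize_monthly <- function(series, rule = c("december", "mean")) {
  stopifnot(inherits(series, "monthly_series"))
  rule <- match.arg(rule)
  if (rule == "december") {
    keep <- series$month == 12L
    stats::setNames(series$value[keep], series$year[keep])
  } else {
    v <- tapply(series$value, series$year, mean)
    stats::setNames(as.numeric(v), names(v))
  }
}
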