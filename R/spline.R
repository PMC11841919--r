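#' Fit an interpolating spline to an annual series
#'
#' Fits one of three piecewise-polynomial interpolants to the (year, value)
#' anchors of a series:
#' \describe{
#'   \item{linear}{chords through consecutive anchors; continuous (C0) but
#'     with a discontinuous derivative at interior knots.}
#'   \item{quadratic}{piecewise quadratics with matching first derivatives
#'     (C1). The knot derivatives follow the recursion
#'     \eqn{D_i = 2 (y_i - y_{i-1})/h_i - D_{i-1}} started from an assumed
#'     initial slope \eqn{D_0}.}
#'   \item{cubic}{the natural cubic spline: C2 everywhere, zero second
#'     derivative at both boundary knots, second-derivative values from a
#'     tridiagonal solve.}
#' }
#'
#' @param x An \code{\link{annual_series}}, or a numeric vector of strictly
#'   increasing knot locations.
#' @param y Knot values (ignored when \code{x} is an annual series).
#' @param method One of \code{"linear"}, \code{"quadratic"}, \code{"cubic"}.
#' @param d0 Assumed initial slope \eqn{f'(x_0)} for the quadratic fit;
#'   defaults to the first secant slope \eqn{(y_1 - y_0)/(x_1 - x_0)}.
#' @return An object of class \code{spline_model} with fields \code{method},
#'   \code{knots}, \code{values}, \code{coef} (one row per piece; columns are
#'   polynomial coefficients in \eqn{(x - x_{i-1})}), and \code{boundary}.
#' @examples
#' s <- annual_series(2000:2005, c(3, 4, 8, 9, 7, 6))
#' m <- fit_spline(s, method = "cubic")
#' eval_spline(m, 2002.5)
#' @export
fit_spline <- function(x, y = NULL,
                       method = c("cubic", "quadratic", "linear"),
                       d0 = NULL) {
  method <- match.arg(method)
  if (inherits(x, "annual_series")) {
    y <- x$values
    x <- as.numeric(x$years)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (any(diff(x) <= 0)) stop("knots must be strictly increasing", call. = FALSE)
  npt <- length(x)
  minpt <- c(linear = 2L, quadratic = 3L, cubic = 4L)[[method]]
  if (npt < minpt) {
    stop(sprintf("method '%s' requires >= %d points", method, minpt), call. = FALSE)
  }
  h <- diff(x)
  n <- npt - 1L  # number of pieces
  boundary <- "natural"
  coef <- switch(method,
    linear = {
      slope <- diff(y) / h
      cbind(c0 = y[-npt], c1 = slope, c2 = 0, c3 = 0)
    },
    quadratic = {
      if (is.null(d0)) d0 <- (y[2] - y[1]) / h[1]
      D <- numeric(npt)
      D[1] <- d0
      for (i in seq_len(n)) D[i + 1L] <- 2 * (y[i + 1L] - y[i]) / h[i] - D[i]
      boundary <- sprintf("clamped(d0=%.17g)", d0)
      cbind(c0 = y[-npt], c1 = D[-npt], c2 = (D[-1L] - D[-npt]) / (2 * h), c3 = 0)
    },
    cubic = {
      M <- natural_second_derivs(x, y)
      slope <- diff(y) / h
      cbind(
        c0 = y[-npt],
        c1 = slope - h * (2 * M[-npt] + M[-1L]) / 6,
        c2 = M[-npt] / 2,
        c3 = (M[-1L] - M[-npt]) / (6 * h)
      )
    }
  )
  structure(
    list(method = method, knots = x, values = y, coef = coef, boundary = boundary),
    class = "spline_model"
  )
}

# Natural-spline second derivatives at the knots via the Thomas algorithm on
# the standard tridiagonal system; M[1] = M[n+1] = 0.
natural_second_derivs <- function(x, y) {
  npt <- length(x)
  h <- diff(x)
  M <- numeric(npt)
  m <- npt - 2L  # interior unknowns
  if (m == 0L) return(M)
  diag_ <- 2 * (h[-length(h)] + h[-1L])
  sub <- h[2:(npt - 2L)]   # length m-1 (empty if m == 1)
  rhs <- 6 * diff(diff(y) / h)
  # forward elimination
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- if (m > 1L) sub[1] / diag_[1] else 0
  dp[1] <- rhs[1] / diag_[1]
  if (m > 1L) {
    for (i in 2:m) {
      denom <- diag_[i] - sub[i - 1L] * cp[i - 1L]
      if (i < m) cp[i] <- sub[i] / denom
      dp[i] <- (rhs[i] - sub[i - 1L] * dp[i - 1L]) / denom
    }
  }
  sol <- numeric(m)
  sol[m] <- dp[m]
  if (m > 1L) for (i in (m - 1L):1L) sol[i] <- dp[i] - cp[i] * sol[i + 1L]
  M[2:(npt - 1L)] <- sol
  M
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf(
    "<spline_model> %s, %d pieces on [%g, %g], boundary: %s\n",
    x$method, nrow(x$coef), min(x$knots), max(x$knots), x$boundary
  ))
  invisible(x)
}

#' Evaluate a fitted spline
#'
#' A query exactly at an interior knot is evaluated on the right-hand piece;
#' continuity makes the value identical either way. Queries outside the knot
#' span are refused unless \code{extrapolate = TRUE}, in which case the
#' terminal piece's polynomial is extended.
#'
#' @param model A \code{spline_model}.
#' @param x Numeric vector of query locations.
#' @param extrapolate Allow evaluation beyond the knot span.
#' @return Numeric vector of spline values.
#' @export
eval_spline <- function(model, x, extrapolate = FALSE) {
  stopifnot(inherits(model, "spline_model"))
  x <- as.numeric(x)
  kn <- model$knots
  n <- nrow(model$coef)
  if (!extrapolate && (any(x < kn[1]) || any(x > kn[length(kn)]))) {
    stop("query outside knot range; set extrapolate = TRUE to extend", call. = FALSE)
  }
  piece <- findInterval(x, kn, all.inside = FALSE)
  piece[piece < 1L] <- 1L
  piece[piece > n] <- n
  dx <- x - kn[piece]
  cf <- model$coef
  unname(cf[piece, 1L] + dx * (cf[piece, 2L] + dx * (cf[piece, 3L] + dx * cf[piece, 4L])))
}

#' @export
predict.spline_model <- function(object, newdata, extrapolate = FALSE, ...) {
  eval_spline(object, newdata, extrapolate = extrapolate)
}

# years the authors retain in the deliberate-deletion protocol
default_kept_years <- c(1990L, 1994L, 1997L, 2001L, 2004L, 2007L,
                        2010L, 2012L, 2014L, 2017L, 2019L, 2021L)

#' Holdout selection of the interpolation method
#'
#' Deliberate-deletion protocol: keep only a subset of the observed years,
#' fit all three spline families to the kept anchors, predict the held-out
#' years with each, and pick the method with minimal holdout MAE. Ties are
#' broken toward the lower-order interpolant (linear < quadratic < cubic).
#'
#' @param series An \code{\link{annual_series}}.
#' @param kept_years Years to retain as anchors (default: the 12-year subset
#'   1990, 1994, 1997, 2001, 2004, 2007, 2010, 2012, 2014, 2017, 2019, 2021,
#'   intersected with the observed years).
#' @return An object of class \code{holdout_report}: kept and held years, a
#'   per-method error table (\code{mae}, \code{rmse}), the winning method,
#'   and any held years that required extrapolation beyond the kept span.
#' @export
holdout_select <- function(series, kept_years = default_kept_years) {
  stopifnot(inherits(series, "annual_series"))
  kept_years <- sort(intersect(as.integer(kept_years), series$years))
  held_years <- setdiff(series$years, kept_years)
  if (length(kept_years) < 4L) stop("need >= 4 kept years", call. = FALSE)
  if (length(held_years) < 1L) stop("need >= 1 held-out year", call. = FALSE)
  ki <- match(kept_years, series$years)
  hi <- match(held_years, series$years)
  xk <- as.numeric(kept_years); yk <- series$values[ki]
  xh <- as.numeric(held_years); yh <- series$values[hi]
  outside <- held_years[xh < min(xk) | xh > max(xk)]
  methods <- c("linear", "quadratic", "cubic")
  tab <- data.frame(method = methods, mae = NA_real_, rmse = NA_real_)
  for (j in seq_along(methods)) {
    fit <- fit_spline(xk, yk, method = methods[j])
    pred <- eval_spline(fit, xh, extrapolate = TRUE)
    e <- yh - pred
    tab$mae[j] <- mean(abs(e))
    tab$rmse[j] <- sqrt(mean(e^2))
  }
  # argmin MAE; near-ties (1e-9 relative) break toward the lower-order method,
  # realized by taking the first qualifying entry of the low-to-high order list
  tied <- tab$mae <= min(tab$mae) * (1 + 1e-9) + 1e-12
  winner <- methods[which(tied)[1]]
  structure(
    list(
      kept_years = kept_years, held_years = held_years,
      errors = tab, winner = winner, extrapolated_years = outside
    ),
    class = "holdout_report"
  )
}

#' @export
print.holdout_report <- function(x, ...) {
  cat(sprintf(
    "<holdout_report> %d kept / %d held years; winner: %s\n",
    length(x$kept_years), length(x$held_years), x$winner
  ))
  print(x$errors, row.names = FALSE)
  if (length(x$extrapolated_years)) {
    cat("held years outside kept span (extrapolated):",
        paste(x$extrapolated_years, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Monthly grid specification
#'
#' @param start Either a string \code{"YYYY-MM"} or an integer vector
#'   \code{c(year, month)}.
#' @param months Total number of consecutive months on the grid.
#' @return A list with \code{start_year}, \code{start_month}, \code{months}.
#' @export
grid_spec <- function(start, months) {
  if (is.character(start)) {
    parts <- as.integer(strsplit(start, "-", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts)) {
      stop("`start` must be 'YYYY-MM' or c(year, month)", call. = FALSE)
    }
    start <- parts
  }
  start <- as.integer(start)
  months <- as.integer(months)
  if (start[2] < 1L || start[2] > 12L) stop("start month must be in 1..12", call. = FALSE)
  if (months < 1L) stop("`months` must be positive", call. = FALSE)
  list(start_year = start[1], start_month = start[2], months = months)
}

#' Expand an annual series to a monthly grid
#'
#' Fits the chosen spline to the annual anchors (each anchor placed at
#' January of its calendar year on a fractional-year axis) and evaluates it
#' on a consecutive monthly grid. Grid months that coincide with an anchor
#' reproduce the annual value exactly and are tagged \code{anchor}; months
#' inside the anchored span are tagged \code{interpolated}; months beyond
#' the last anchor are produced by extending the terminal polynomial piece
#' and tagged \code{extrapolated}.
#'
#' The default grid starts at January of the first anchor year and spans 420
#' months, so a 32-anchor 1990--2021 series expands to 420 monthly entries.
#'
#' @param series An \code{\link{annual_series}}.
#' @param method Spline family to use (see \code{\link{fit_spline}}).
#' @param grid A \code{\link{grid_spec}}; default
#'   \code{grid_spec(c(first_year, 1), 420)}.
#' @return A \code{\link{monthly_series}} of exactly \code{grid$months}
#'   entries.
#' @export
expand_monthly <- function(series, method = c("cubic", "quadratic", "linear"),
                           grid = NULL) {
  stopifnot(inherits(series, "annual_series"))
  method <- match.arg(method)
  if (is.null(grid)) grid <- grid_spec(c(series$years[1], 1L), 420L)
  fit <- fit_spline(series, method = method)
  first_anchor <- series$years[1]  # anchors sit at January
  if (grid$start_year + (grid$start_month - 1) / 12 < first_anchor) {
    stop("grid starts before the first anchor", call. = FALSE)
  }
  midx <- (grid$start_year * 12L + grid$start_month - 1L) + 0:(grid$months - 1L)
  year <- midx %/% 12L
  month <- midx %% 12L + 1L
  xq <- year + (month - 1L) / 12
  value <- eval_spline(fit, xq, extrapolate = TRUE)
  src <- ifelse(xq > max(fit$knots), "extrapolated", "interpolated")
  is_anchor <- month == 1L & year %in% series$years
  value[is_anchor] <- series$values[match(year[is_anchor], series$years)]
  src[is_anchor] <- "anchor"
  monthly_series(year, month, value, src)
}
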