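#' Sliding-window supervised dataset
#'
#' Converts driving series plus a target series into the windowed NARX form:
#' for every time point \eqn{t \in [\tau, T]} one sample holding the driver
#' window \eqn{x_{t-\tau+1..t}} (all \eqn{n} series), the past targets
#' \eqn{y_{t-\tau+1..t-1}}, and the label \eqn{y_t}. Samples are kept in
#' chronological order; there are exactly \eqn{T - \tau + 1} of them.
#'
#' @param drivers Numeric matrix of exogenous driving series, \code{T} rows
#'   (time steps) by \code{n} columns (series). A vector is treated as a
#'   single series.
#' @param targets Numeric target series of length \code{T}.
#' @param tau Window length, \code{1 <= tau < T}.
#' @return An object of class \code{windowed_dataset}: \code{windows} (array
#'   \code{n x tau x S}), \code{past} (matrix \code{(tau-1) x S}),
#'   \code{labels} (length \code{S}), plus \code{tau}, \code{n} and the
#'   original time index of each label.
#' @examples
#' d <- matrix(rnorm(40), 20, 2)
#' ds <- make_windows(d, rowSums(d), tau = 4)
#' ds$n_samples  # 17
#' @export
make_windows <- function(drivers, targets, tau) {
  if (is.vector(drivers)) drivers <- matrix(drivers, ncol = 1L)
  drivers <- as.matrix(drivers)
  targets <- as.numeric(targets)
  T_ <- length(targets)
  if (nrow(drivers) != T_) {
    stop("`drivers` must have one row per target time step", call. = FALSE)
  }
  tau <- as.integer(tau)
  if (tau < 1L || tau >= T_) stop("need 1 <= tau < T", call. = FALSE)
  n <- ncol(drivers)
  S <- T_ - tau + 1L
  windows <- array(0, dim = c(n, tau, S))
  past <- matrix(0, max(tau - 1L, 1L), S)
  labels <- numeric(S)
  for (s in seq_len(S)) {
    t <- tau + s - 1L
    windows[, , s] <- t(drivers[(t - tau + 1L):t, , drop = FALSE])
    if (tau > 1L) past[, s] <- targets[(t - tau + 1L):(t - 1L)]
    labels[s] <- targets[t]
  }
  if (tau == 1L) past <- matrix(0, 0L, S)
  structure(
    list(
      windows = windows, past = past, labels = labels,
      tau = tau, n = n, n_samples = S, t_index = tau:T_
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d samples, %d driver(s), window tau = %d\n",
    x$n_samples, x$n, x$tau
  ))
  invisible(x)
}

#' Chronological train/validation/test split
#'
#' The final \code{test} labels form the test set, the preceding \code{val}
#' labels the validation set, and everything earlier the training set.
#'
#' @param dataset A \code{\link{make_windows}} result.
#' @param test,val Number of samples in the test and validation blocks.
#' @return List of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
split_windows <- function(dataset, test = 36L, val = 36L) {
  S <- dataset$n_samples
  test <- as.integer(test); val <- as.integer(val)
  if (test < 1L || val < 0L || test + val >= S) {
    stop("split leaves no training samples", call. = FALSE)
  }
  list(
    train = seq_len(S - test - val),
    val = if (val > 0L) (S - test - val + 1L):(S - test) else integer(),
    test = (S - test + 1L):S
  )
}

# subset samples of a windowed dataset
ds_take <- function(dataset, idx) {
  list(
    windows = dataset$windows[, , idx, drop = FALSE],
    past = dataset$past[, idx, drop = FALSE],
    labels = dataset$labels[idx],
    tau = dataset$tau, n = dataset$n, n_samples = length(idx)
  )
}

# z-score scaling statistics estimated on the training samples only
ds_scaler <- function(dataset, train_idx) {
  xs <- dataset$windows[, , train_idx, drop = FALSE]
  mu_x <- apply(xs, 1L, mean)
  sd_x <- apply(xs, 1L, stats::sd)
  sd_x[sd_x == 0 | !is.finite(sd_x)] <- 1
  y_tr <- dataset$labels[train_idx]
  mu_y <- mean(y_tr)
  sd_y <- stats::sd(y_tr)
  if (sd_y == 0 || !is.finite(sd_y)) sd_y <- 1
  list(mu_x = mu_x, sd_x = sd_x, mu_y = mu_y, sd_y = sd_y)
}

ds_standardize <- function(dataset, scaler) {
  out <- dataset
  out$windows <- (dataset$windows - scaler$mu_x) / scaler$sd_x  # recycles over dims 2,3
  if (nrow(dataset$past) > 0L) {
    out$past <- (dataset$past - scaler$mu_y) / scaler$sd_y
  }
  out$labels <- (dataset$labels - scaler$mu_y) / scaler$sd_y
  out
}
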