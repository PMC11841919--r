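# finite-difference continuity probes at an interior knot
fd_deriv <- function(model, x0, order = 1L, h = 1e-4) {
  f <- function(x) eval_spline(model, x)
  if (order == 1L) (f(x0 + h) - f(x0 - h)) / (2 * h)
  else (f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2
}

side_deriv <- function(model, x0, side, order = 1L, h = 1e-5) {
  f <- function(x) eval_spline(model, x)
  s <- if (side == "left") -1 else 1
  if (order == 1L) s * (f(x0 + s * 2 * h) - 4 * f(x0 + s * h) + 3 * f(x0)) / (-2 * h)
  else (f(x0) - 2 * f(x0 + s * h) + f(x0 + s * 2 * h)) / h^2
}

test_that("linear spline is the chord through its endpoints", {
  m <- fit_spline(c(0, 2), c(0, 4), "linear")
  expect_equal(eval_spline(m, 1), 2)
  set.seed(1)
  x <- sort(runif(20, 0, 100)); y <- rnorm(20)
  m <- fit_spline(x, y, "linear")
  expect_equal(eval_spline(m, x), y, tolerance = 1e-12)
  xq <- runif(200, min(x), max(x))
  # direct two-point formula oracle
  oracle <- vapply(xq, function(q) {
    i <- max(which(x <= q)); i <- min(i, length(x) - 1)
    y[i] + (y[i + 1] - y[i]) * (q - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
  expect_equal(eval_spline(m, xq), oracle, tolerance = 1e-12)
})

test_that("quadratic spline follows the derivative recursion and is C1", {
  # anchors (0,0),(1,1),(2,4) with d0 = 0: D1 = 2, D2 = 4 by hand
  m <- fit_spline(c(0, 1, 2), c(0, 1, 4), "quadratic", d0 = 0)
  expect_equal(unname(m$coef[, "c1"]), c(0, 2))  # D0, D1
  expect_equal(unname(m$coef[2, "c1"] + 2 * m$coef[2, "c2"] * 1), 4)  # D2

  # straight-line data with the true slope: spline is the line
  xs <- 0:6; ys <- 3 + 2 * xs
  ml <- fit_spline(xs, ys, "quadratic", d0 = 2)
  xq <- runif(50, 0, 6)
  expect_equal(eval_spline(ml, xq), 3 + 2 * xq, tolerance = 1e-10)

  # C1 at interior knots on random data (one-sided finite differences)
  set.seed(2)
  x <- sort(runif(8, 0, 10)); y <- rnorm(8)
  mr <- fit_spline(x, y, "quadratic")
  for (k in 2:(length(x) - 1)) {
    expect_equal(side_deriv(mr, x[k], "left"), side_deriv(mr, x[k], "right"),
                 tolerance = 1e-4)
  }
})

test_that("natural cubic spline interpolates, reproduces lines, and matches stats::spline", {
  # collinear data: natural spline is exactly the line
  x <- c(0, 1, 3, 4, 7); y <- 2 + 5 * x
  m <- fit_spline(x, y, "cubic")
  xq <- seq(0, 7, length.out = 60)
  expect_equal(eval_spline(m, xq), 2 + 5 * xq, tolerance = 1e-10)

  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- sort(runif(n, 0, 50))
    y <- rnorm(n, 10, 4)
    m <- fit_spline(x, y, "cubic")
    expect_equal(eval_spline(m, x), y, tolerance = 1e-9)
    xq <- runif(100, min(x), max(x))
    ref <- stats::spline(x, y, method = "natural", xout = xq)$y
    expect_equal(eval_spline(m, xq), ref, tolerance = 1e-9)
  }
})

test_that("continuity classes hold at interior knots (C0/C1/C2)", {
  set.seed(4)
  x <- sort(sample(1:60, 9)); y <- rnorm(9, 0, 3)
  for (method in c("linear", "quadratic", "cubic")) {
    m <- fit_spline(x, y, method)
    expect_equal(eval_spline(m, x), y, tolerance = 1e-9)  # C0 everywhere
    if (method %in% c("quadratic", "cubic")) {
      for (k in 2:(length(x) - 1)) {
        expect_equal(side_deriv(m, x[k], "left"), side_deriv(m, x[k], "right"),
                     tolerance = 1e-4)
      }
    }
    if (method == "cubic") {
      for (k in 2:(length(x) - 1)) {
        expect_equal(side_deriv(m, x[k], "left", order = 2L),
                     side_deriv(m, x[k], "right", order = 2L),
                     tolerance = 1e-3)
      }
    }
  }
})

test_that("evaluation respects the knot range unless extrapolating", {
  m <- fit_spline(0:4, c(0, 1, 0, 1, 0), "cubic")
  expect_error(eval_spline(m, 5), "outside")
  # terminal-piece extension is continuous at the last knot
  expect_equal(eval_spline(m, 4 + 1e-9, extrapolate = TRUE),
               eval_spline(m, 4), tolerance = 1e-6)
  # batch evaluation equals a loop of scalar evaluations
  xq <- seq(-1, 6, by = 0.37)
  expect_equal(eval_spline(m, xq, extrapolate = TRUE),
               vapply(xq, function(q) eval_spline(m, q, extrapolate = TRUE),
                      numeric(1)))
})

test_that("spline fits enforce minimum point counts", {
  expect_error(fit_spline(1, 1, "linear"), ">= 2")
  expect_error(fit_spline(1:2, 1:2, "quadratic"), ">= 3")
  expect_error(fit_spline(1:3, 1:3, "cubic"), ">= 4")
})

test_that("holdout selection picks the cubic on cubic data and the oracle agrees", {
  rep_ <- holdout_select(fix_cubic_series())
  expect_equal(rep_$winner, "cubic")
  maes <- stats::setNames(rep_$errors$mae, rep_$errors$method)
  expect_lt(maes[["cubic"]], min(maes[["linear"]], maes[["quadratic"]]))
  expect_lt(maes[["cubic"]], 0.05)  # near-exact inside the span
  expect_length(intersect(rep_$kept_years, rep_$held_years), 0L)

  # brute-force recompute-and-argmin oracle on random smooth series
  set.seed(9)
  for (rep in 1:10) {
    yrs <- 1990:2021
    k <- yrs - 1990
    vals <- 100 + runif(1, 0.2, 1) * k + runif(1, -0.02, 0.05) * k^2 +
      2 * sin(k / runif(1, 2, 6)) + 10
    s <- annual_series(yrs, vals)
    rp <- holdout_select(s)
    kept <- rp$kept_years; held <- rp$held_years
    maes <- vapply(c("linear", "quadratic", "cubic"), function(mm) {
      fit <- fit_spline(as.numeric(kept), s$values[match(kept, s$years)], mm)
      mean(abs(s$values[match(held, s$years)] -
                 eval_spline(fit, as.numeric(held), extrapolate = TRUE)))
    }, numeric(1))
    expect_equal(rp$winner, names(which.min(maes)))
    expect_equal(unname(maes), rp$errors$mae, tolerance = 1e-12)
  }
})

test_that("holdout ties on affine data break toward the linear method", {
  yrs <- 1990:2021
  s <- annual_series(yrs, 100 + 2 * (yrs - 1990))
  rp <- holdout_select(s)
  expect_true(all(rp$errors$mae < 1e-8))
  expect_equal(rp$winner, "linear")
})

test_that("monthly expansion is gap-free, length-exact and anchor-exact", {
  s <- fix_cubic_series()
  m <- expand_monthly(s, "cubic")
  expect_length(m, 420L)
  expect_equal(sum(m$source == "anchor"), 32L)
  anchor_vals <- m$value[m$source == "anchor"]
  expect_identical(anchor_vals, s$values)  # bit-for-bit
  expect_true(all(m$source[m$year > 2021] == "extrapolated"))

  # two anchors one year apart, linear method, 13-month grid: arithmetic progression
  s2 <- annual_series(c(2000L, 2001L), c(10, 22))
  m2 <- expand_monthly(s2, "linear", grid = grid_spec("2000-01", 13))
  expect_length(m2, 13L)
  expect_equal(diff(m2$value), rep(1, 12), tolerance = 1e-9)

  expect_error(
    expand_monthly(s2, "linear", grid = grid_spec("1999-01", 13)),
    "before the first anchor"
  )
})
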