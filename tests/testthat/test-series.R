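test_that("annual_series enforces its invariants", {
  expect_s3_class(annual_series(2000:2002, c(1, 2, 3)), "annual_series")
  expect_error(annual_series(c(2000, 2000, 2001), c(1, 2, 3)), "increasing")
  expect_error(annual_series(2000:2002, c(1, -2, 3)), "non-negative")
  expect_error(annual_series(2000:2002, c(1, 2)), "equal length")
  expect_error(annual_series(2000:2002, c(1, NA, 3)), "finite")
})

test_that("monthly_series requires a gap-free consecutive index", {
  m <- monthly_series(c(2000, 2000, 2001), c(11, 12, 1), 1:3,
                      rep("interpolated", 3))
  expect_length(m, 3L)
  expect_error(
    monthly_series(c(2000, 2000), c(1, 3), 1:2, rep("anchor", 2)),
    "consecutive"
  )
  expect_error(
    monthly_series(2000, 13, 1, "anchor"), "1..12"
  )
  expect_error(
    monthly_series(2000, 1, 1, "guessed"), "source tag"
  )
})

test_that("forecast errors are elementwise differences", {
  expect_equal(forecast_errors(3, 2), 1)
  y <- c(1.5, 2, 8)
  expect_equal(forecast_errors(y, y), c(0, 0, 0))
  expect_error(forecast_errors(1:3, 1:2), "equal length")
  expect_error(forecast_errors(c(1, NA), c(1, 2)), "finite")
})

test_that("forecast errors match a brute-force loop oracle and are anti-symmetric", {
  set.seed(42)
  for (rep in 1:5) {
    a <- rnorm(50); p <- rnorm(50)
    oracle <- vapply(seq_along(a), function(i) a[i] - p[i], numeric(1))
    expect_identical(forecast_errors(a, p), oracle)
    expect_identical(forecast_errors(a, p), -forecast_errors(p, a))
  }
})

test_that("metrics agree with direct-summation oracles", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    a <- rnorm(n, 50, 5); p <- a + rnorm(n)
    tr <- rnorm(n + 5, 50, 5)
    m <- compute_metrics(a, p, tr)
    e <- a - p
    expect_equal(m$rmse, sqrt(sum(e^2) / n), tolerance = 1e-12)
    expect_equal(m$mae, sum(abs(e)) / n, tolerance = 1e-12)
    expect_equal(m$mape, 100 * sum(abs(e / a)) / n, tolerance = 1e-12)
    expect_equal(m$mase, (sum(abs(e)) / n) /
                   (sum(abs(tr[-1] - tr[-length(tr)])) / (length(tr) - 1)),
                 tolerance = 1e-12)
    expect_equal(m$accuracy, 100 - m$mape)
    expect_equal(m$error_pct, m$mape)
  }
})

test_that("perfect forecasts score zero error and full accuracy", {
  y <- c(5, 6, 7.5)
  m <- compute_metrics(y, y, training = y)
  expect_equal(m$rmse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$mape, 0)
  expect_equal(m$accuracy, 100)
})

test_that("the one-step naive forecaster scores MASE 1 on its own training series", {
  set.seed(3)
  y <- cumsum(rnorm(30)) + 50
  nv <- naive_one_step(y)
  m <- compute_metrics(nv$actual, nv$predicted, training = y)
  expect_equal(m$mase, 1, tolerance = 1e-12)
})

test_that("metrics are scale-consistent", {
  set.seed(11)
  a <- rnorm(20, 40, 3); p <- a + rnorm(20)
  tr <- rnorm(25, 40, 3)
  m1 <- compute_metrics(a, p, tr)
  m2 <- compute_metrics(7 * a, 7 * p, 7 * tr)
  expect_equal(m2$rmse, 7 * m1$rmse, tolerance = 1e-12)
  expect_equal(m2$mae, 7 * m1$mae, tolerance = 1e-12)
  expect_equal(m2$mape, m1$mape, tolerance = 1e-12)
  expect_equal(m2$mase, m1$mase, tolerance = 1e-12)
})

test_that("metric preconditions are enforced", {
  expect_error(compute_metrics(c(0, 1), c(1, 1), 1:5), "MAPE undefined")
  expect_error(compute_metrics(1, 1, training = 2), "at least 2")
})

test_that("annual CSV round-trips and rejects malformed files", {
  path <- tempfile(fileext = ".csv")
  s <- fix_annual(n = 8)
  write_annual_csv(s, path)
  s2 <- read_annual_csv(path)
  expect_identical(s2$years, s$years)
  expect_identical(s2$values, s$values)

  writeLines(c("year,value", "2000,1", "2000,2"), path)
  expect_error(read_annual_csv(path), "increasing")
  writeLines(c("year,value", "2000,1", "2001,abc"), path)
  expect_error(read_annual_csv(path), "non-numeric")
  writeLines(c("year,other", "2000,1"), path)
  expect_error(read_annual_csv(path), "value")
})

test_that("a 420-entry monthly series round-trips bit-exactly", {
  m <- expand_monthly(fix_cubic_series(), method = "cubic")
  path <- tempfile(fileext = ".csv")
  write_monthly_csv(m, path)
  m2 <- read_monthly_csv(path)
  expect_identical(m2$year, m$year)
  expect_identical(m2$month, m$month)
  expect_identical(m2$value, m$value)
  expect_identical(m2$source, m$source)
})
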