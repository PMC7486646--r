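test_that("white-noise fits give near-zero coefficients", {
  set.seed(21)
  x <- rnorm(2000)
  f <- fit_ma(x, 2)
  expect_true(all(abs(f$theta) < 0.07))
  expect_equal(f$n_obs, 2000L)
  expect_equal(length(f$residuals), 2000L)
})

test_that("MA(1) recovery matches a brute-force CSS grid and stats::arima", {
  x <- sim_ma1(2000, 0.6, seed = 42)
  f <- fit_ma(x, 1)
  expect_gt(f$theta[[1]], 0.55)
  expect_lt(f$theta[[1]], 0.65)

  # independent oracle 1: coarse grid over theta must not beat the optimum
  # by more than 0.1%
  grid <- seq(0.40, 0.80, by = 0.001)
  sse_grid <- vapply(grid, function(th) css_oracle(x, th), numeric(1))
  expect_lt(sum(f$residuals^2), min(sse_grid) * 1.001)
  expect_lt(abs(grid[which.min(sse_grid)] - f$theta[[1]]), 0.002)

  # independent oracle 2: stats::arima CSS, opposite sign convention
  ref <- arima(x, order = c(0, 0, 1), include.mean = FALSE, method = "CSS")
  expect_equal(unname(f$theta[1]), unname(-coef(ref)[1]), tolerance = 1e-4)
})

test_that("fitted polynomials are always invertible", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(300) + 0.5 * sin(1:300)
    f <- fit_ma(x, 4)
    roots <- polyroot(c(1, -f$theta))
    expect_true(all(Mod(roots) > 1))
  }
})

test_that("BIC selects the generating order and penalises excess", {
  hits <- vapply(1:50, function(s) select_order(sim_ma1(400, 0.6, s), 1:7)$q,
                 numeric(1))
  expect_gte(mean(hits == 1), 0.8)

  # a strong lag-7-only coefficient wins the order-7 fit over order 1,
  # confirmed by comparing the oracle CSS at both orders
  set.seed(77)
  e <- rnorm(1007)
  x7 <- e[-(1:7)] - 0.7 * e[1:1000]
  f <- select_order(x7, c(1, 7))
  expect_equal(f$q, 7L)
  expect_lt(css_oracle(x7, c(rep(0, 6), 0.7)), css_oracle(x7, 0.3))

  # single candidate is returned unconditionally
  expect_equal(select_order(rnorm(100), 2)$q, 2L)
})

test_that("Ljung-Box reproduces Q, df and p structure", {
  set.seed(31)
  r <- rnorm(400)
  out <- ljung_box(r, lags = c(6, 12, 18, 24, 30), fitdf = 7)
  expect_equal(out$df, c(0L, 5L, 11L, 17L, 23L))
  expect_true(is.na(out$p_value[1]))
  expect_false(anyNA(out$p_value[-1]))

  # statistic agrees with the reference implementation at every lag
  for (i in 2:5) {
    ref <- Box.test(r, lag = out$lag[i], type = "Ljung-Box", fitdf = 7)
    expect_equal(out$statistic[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(out$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("Ljung-Box holds size under the null and has power under AR(1)", {
  keep <- vapply(1:40, function(s) {
    set.seed(s)
    ljung_box(rnorm(1000), lags = 12, fitdf = 0)$p_value > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.85)   # ~95% expected at the 5% level

  set.seed(8)
  ar <- as.numeric(arima.sim(list(ar = 0.7), n = 1000))
  expect_lt(ljung_box(ar, lags = 12, fitdf = 0)$p_value, 0.01)
})

test_that("MA forecasts vanish beyond the model order", {
  x <- sim_ma1(500, 0.6, seed = 3)
  f <- fit_ma(x, 1)
  fc <- predict(f, h = 7)
  expect_true(all(fc[2:7] == 0))
  expect_false(fc[1] == 0)
})

test_that("level forecasts are accurate end to end on low-noise data", {
  cfg <- sim_config(n_weeks = 30, noise_sd = 20, holiday_rate = 0,
                    annual_amplitude = 0.05)
  s <- simulate_counts(cfg, seed = 6)
  y <- s$count[1:196]                      # fit on 28 weeks
  w <- difference(y, d = 1, D = 1, s = 7)
  f <- fit_ma(w, 7)
  fc <- forecast_arima(y, f, d = 1, D = 1, s = 7, horizon = 7)
  expect_lt(mape(s$count[197:203], fc), 2)
  expect_error(forecast_arima(y, f, horizon = 8), "capped at 7")
})
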