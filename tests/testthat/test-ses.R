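test_that("initial level is the mean of the first three weeks", {
  expect_equal(ses_init_level(c(100, 110, 120, 500, 600)), 110)
  expect_equal(ses_init_level(rep(42, 5)), 42)
  expect_equal(ses_init_level(c(5387, 5155, 5095)), 5212.333, tolerance = 1e-4)
  expect_error(ses_init_level(c(1, 2)), "at least 3 weeks")
})

test_that("the smoothing recursion matches hand arithmetic", {
  f <- ses_smooth(c(10, 12), alpha = 0.5, initial_level = 10)
  expect_equal(f$smoothed, c(10, 10))
  expect_equal(f$forecast_next, 11)

  # constant series is a fixed point for any alpha
  for (a in c(0.01, 0.5, 0.99)) {
    g <- ses_smooth(rep(7, 6), alpha = a, initial_level = 7)
    expect_equal(g$smoothed, rep(7, 6))
    expect_equal(g$forecast_next, 7)
  }

  # alpha near 1 tracks the last observation
  set.seed(2)
  x <- 100 + cumsum(rnorm(20))
  h <- ses_smooth(x, alpha = 0.999)
  expect_lt(abs(h$forecast_next - x[20]) / x[20], 0.002)

  expect_error(ses_smooth(1:5, alpha = 1), "strictly inside")
  expect_error(ses_smooth(1:5, alpha = 0), "strictly inside")
})

test_that("smoothed values are convex combinations with weights summing to 1", {
  # expand the recursion symbolically for 5 steps: the weight on the
  # initial level is (1-a)^(w-1) and on observation j < w is a (1-a)^(w-1-j)
  a <- 0.3
  x <- c(50, 80, 20, 90, 60)
  f <- ses_smooth(x, alpha = a, initial_level = 40)
  for (w in 1:5) {
    wts <- c((1 - a)^(w - 1),
             if (w > 1) a * (1 - a)^((w - 2):0) else numeric())
    expect_equal(sum(wts), 1)
    expect_equal(f$smoothed[w], sum(wts * c(40, x[seq_len(w - 1)])))
    expect_gte(f$smoothed[w], min(40, x[seq_len(max(w - 1, 1))]))
    expect_lte(f$smoothed[w], max(40, x[seq_len(max(w - 1, 1))]))
  }
})

test_that("shifting the series by a constant shifts the fit by the same", {
  set.seed(5)
  x <- 100 + rnorm(12, sd = 10)
  f <- ses_smooth(x, alpha = 0.4)
  g <- ses_smooth(x + 55, alpha = 0.4)
  expect_equal(g$smoothed, f$smoothed + 55)
  expect_equal(g$forecast_next, f$forecast_next + 55)
})

test_that("grid selection agrees with an exhaustive oracle", {
  grid <- seq(0.001, 0.999, by = 0.001)
  for (seed in 1:20) {
    set.seed(seed)
    # slowly drifting level, the regime exponential smoothing is built for
    level <- 1000 + cumsum(rnorm(15, sd = 20))
    x <- level + rnorm(15, sd = 30)
    got <- select_alpha(x, grid = grid)
    oracle <- grid[which.min(vapply(grid, function(a) ses_mse_oracle(x, a),
                                    numeric(1)))]
    expect_equal(got, oracle)
  }
})

test_that("flat objectives break ties toward the smaller alpha", {
  expect_equal(select_alpha(rep(100, 8)), 0.001)
})

test_that("stationary noise favours small smoothing constants", {
  low_half <- vapply(1:50, function(s) {
    set.seed(s)
    select_alpha(rnorm(30, 500, 40)) < 0.5
  }, logical(1))
  expect_gte(mean(low_half), 0.8)
})

test_that("per-weekday forecasts reduce to column-wise smoothing", {
  s <- simulate_counts(noiseless_config(6), seed = 1)
  p <- to_panel(s)
  fit <- forecast_ses(p, alphas = "auto")
  expect_equal(unname(fit$forecast), as.numeric(p[1, ]))  # constant columns

  set.seed(9)
  p2 <- to_panel(simulate_counts(sim_config(n_weeks = 8), seed = 9))
  manual <- c(0.099, 0.200, 0.006, 0.100, 0.003, 0.027, 0.199)
  fit2 <- forecast_ses(p2, alphas = manual)
  expect_equal(unname(fit2$alphas), manual)
  for (tau in 1:7) {
    ref <- ses_smooth(p2[, tau], alpha = manual[tau])
    expect_equal(unname(fit2$forecast[tau]), ref$forecast_next)
  }

  expect_error(forecast_ses(to_panel(simulate_counts(sim_config(n_weeks = 3),
                                                     seed = 1))),
               "at least 4 weeks")
})
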