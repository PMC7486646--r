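# independent oracles and fixture builders, deliberately written as plain
# loops so they share no code path with the implementation they check

# generator config with all stochastic elements off: the series equals its
# mean function exactly (up to integer rounding of the counts)
noiseless_config <- function(n_weeks, base_level = 100,
                             profile = c(1, 1, 1, 1, 1, 0.5, 0.2),
                             trend_slope = 0, annual_amplitude = 0) {
  sim_config(n_weeks = n_weeks, base_level = base_level,
             weekday_profile = profile, annual_amplitude = annual_amplitude,
             trend_slope = trend_slope, noise_sd = 0, holiday_rate = 0)
}

# conditional sum of squares of the MA(q) model, plain recursion
css_oracle <- function(x, theta) {
  q <- length(theta)
  e <- numeric(length(x))
  for (t in seq_along(x)) {
    acc <- x[t]
    for (j in seq_len(min(q, t - 1))) acc <- acc + theta[j] * e[t - j]
    e[t] <- acc
  }
  sum(e^2)
}

# SES one-step error objective (weeks 4..n), plain recursion
ses_mse_oracle <- function(x, alpha, init = mean(x[1:3])) {
  s <- init
  sse <- 0
  for (w in seq_along(x)) {
    if (w >= 4) sse <- sse + (x[w] - s)^2
    s <- alpha * x[w] + (1 - alpha) * s
  }
  sse / (length(x) - 3)
}

# combined squared error at ARIMA weight w1, for brute-force weight search
comb_sse <- function(w1, e1, e2) sum((w1 * e1 + (1 - w1) * e2)^2)

# simulate MA(1) data under the package's sign convention
# x_t = e_t - theta * e_{t-1}
sim_ma1 <- function(n, theta, seed) {
  set.seed(seed)
  e <- rnorm(n + 1)
  e[-1] - theta * e[-(n + 1)]
}
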