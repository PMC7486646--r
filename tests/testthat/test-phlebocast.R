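fit_small <- function(seed = 1, n_weeks = 16, ...) {
  phlebocast(simulate_counts(sim_config(n_weeks = n_weeks), seed = seed), ...)
}

test_that("the fit bundles both components, weights and a 7-day forecast", {
  fit <- fit_small()
  expect_s3_class(fit, "phlebocast")
  expect_s3_class(fit$ma_fit, "ma_css")
  expect_s3_class(fit$ses_fit, "ses_panel_fit")
  expect_s3_class(fit$weights, "comb_weights")
  expect_equal(fit$weights$w1 + fit$weights$w2, 1)
  expect_true(fit$weights$w1 >= 0 && fit$weights$w1 <= 1)

  fc <- predict(fit)
  expect_length(fc, 7L)
  expect_named(fc, c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  all3 <- predict(fit, model = "all")
  expect_equal(all3$combined,
               fit$weights$w1 * all3$arima + fit$weights$w2 * all3$ses)
  expect_equal(weekday_index(all3$date[1]), 1L)  # forecast week starts Monday

  cf <- coef(fit)
  expect_length(cf, fit$ma_fit$q + 7 + 2)
  expect_equal(unname(cf["w1"]), fit$weights$w1)
})

test_that("residual accessors agree with their definitions", {
  fit <- fit_small(seed = 3)
  y <- fit$series$count[fit$window]
  e1 <- residuals(fit, "arima")
  e2 <- residuals(fit, "ses")
  ec <- residuals(fit, "combined")
  expect_equal(ec, fit$weights$w1 * e1 + fit$weights$w2 * e2)
  expect_equal(fitted(fit, "combined"), y - ec)
  # the window excludes the differencing burn-in and the 3-week SES warm-up
  expect_true(min(fit$window) > fit$spec$d + fit$spec$D * fit$spec$s)
  expect_true(min((fit$window - 1) %/% 7 + 1) >= 4)
})

test_that("fits are deterministic and honour manual settings", {
  expect_equal(predict(fit_small(seed = 5)), predict(fit_small(seed = 5)))

  # manual w1 = 1 collapses the combination onto the ARIMA component
  fit1 <- fit_small(seed = 5, weights = manual_weights(1))
  expect_equal(predict(fit1, "combined"), predict(fit1, "arima"))

  manual <- c(0.099, 0.2, 0.006, 0.1, 0.003, 0.027, 0.199)
  fit2 <- fit_small(seed = 5, alpha = manual)
  expect_equal(unname(fit2$ses_fit$alphas), manual)
})

test_that("summary assembles diagnostics without refitting", {
  fit <- fit_small(seed = 2)
  sm <- summary(fit)
  expect_equal(nrow(sm$coef_table), fit$ma_fit$q)
  expect_equal(sm$ljung_box$df, pmax(sm$ljung_box$lag - fit$ma_fit$q, 0L))
  expect_equal(nrow(sm$ses_table), 7L)
  expect_true(all(sm$in_sample_mape > 0))
  expect_output(print(sm), "Ljung-Box")
})

test_that("BIC order search and log transform are usable from the top level", {
  s <- simulate_counts(sim_config(n_weeks = 16), seed = 8)
  fit <- phlebocast(s, q_candidates = c(1, 7))
  expect_true(fit$ma_fit$q %in% c(1L, 7L))
  expect_s3_class(attr(fit$ma_fit, "bic_table"), "data.frame")

  fitl <- phlebocast(s, log_transform = TRUE)
  expect_true(all(predict(fitl, "arima") > 0))
})

test_that("preprocessing inside the fit removes injected outliers", {
  s <- simulate_counts(sim_config(n_weeks = 16, noise_sd = 50,
                                  holiday_rate = 0), seed = 4)
  inj <- inject_singularities(s, k = 3, magnitude = 4, seed = 2)
  fit <- phlebocast(inj$series, preprocess = TRUE)
  # every injected day is among the replacements (genuine noise outliers
  # beyond 2 SDs may be flagged as well)
  injected <- paste(inj$positions$week, inj$positions$day)
  flagged <- paste(fit$replacements$week, fit$replacements$day)
  expect_true(all(injected %in% flagged))
  expect_false(identical(fit$series$count, inj$series$count))
})
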