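Package: phlebocast
Title: Hybrid ARIMA and Per-Weekday Exponential Smoothing Forecasts of
    Daily Blood-Collection Demand
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-week-ahead forecasting of daily outpatient
    blood-sampling-room visit counts. Combines a seasonally differenced
    moving-average model fitted by conditional least squares with one
    simple-exponential-smoothing model per day of the week, weighting the
    two forecasts by constrained least squares on their in-sample
    residuals (residual correction). Includes a calibrated synthetic
    series generator, per-weekday two-standard-deviation outlier
    replacement, Ljung-Box diagnostics, and a rolling one-week-ahead
    evaluation protocol scored by mean absolute percentage error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
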