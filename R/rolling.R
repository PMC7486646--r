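#' Rolling one-week-ahead evaluation
#'
#' Evaluates the three models (ARIMA, SES, combined) under the rolling
#' protocol: for each test week `w`, all models are refitted — and the
#' combination weights re-estimated — on the data through week `w - 1`
#' only, the next seven days are forecast, and the forecasts are scored
#' against the observed week with [week_report()].  The pooled summary
#' averages per-day absolute percentage errors across the test weeks; its
#' overall, workday and weekend columns are the means of the pooled
#' per-day values.
#'
#' @param x a `daily_counts` object covering at least
#'   `n_test_weeks + 5` whole weeks (the fitting window must support the
#'   MA order and the SES initialisation).
#' @param n_test_weeks number of final weeks held out and forecast one at
#'   a time (default 8).
#' @param ... fitting arguments passed on to [phlebocast()] at every
#'   origin (`d`, `D`, `q`, `alpha`, `weight_method`, ...).
#' @return object of class `rolling_eval`: list with `reports` (per model,
#'   a list of `week_report`s, one per test week), `pooled` (matrix of
#'   models by Mon..Sun/Overall/Workday/Weekend, in percent), `weights`
#'   (per-origin estimated `w1`), and `test_weeks`.
#' @examples
#' \donttest{
#' s <- simulate_counts(sim_config(n_weeks = 16), seed = 1)
#' rolling_evaluate(s, n_test_weeks = 2)
#' }
#' @export
rolling_evaluate <- function(x, n_test_weeks = 8L, ...) {
  if (!inherits(x, "daily_counts")) x <- daily_counts(x$date, x$count)
  x <- trim_to_whole_weeks(x)
  n_weeks <- nrow(x) %/% 7L
  if (n_test_weeks < 1L) stop("'n_test_weeks' must be at least 1")
  first_test <- n_weeks - n_test_weeks + 1L
  if (first_test < 6L)
    stop("series too short: ", n_weeks, " weeks leaves fewer than 5 ",
         "fitting weeks before the first test week")
  models <- c("arima", "ses", "combined")
  reports <- stats::setNames(
    lapply(models, function(m) vector("list", n_test_weeks)), models)
  w1 <- numeric(n_test_weeks)
  for (i in seq_len(n_test_weeks)) {
    wk <- first_test + i - 1L
    fit_days <- seq_len(7L * (wk - 1L))
    test_days <- 7L * (wk - 1L) + 1:7
    fit <- phlebocast(daily_counts(x$date[fit_days], x$count[fit_days]), ...)
    obs <- x$count[test_days]
    for (m in models)
      reports[[m]][[i]] <- week_report(obs, predict(fit, model = m))
    w1[i] <- fit$weights$w1
  }
  pooled <- t(vapply(models, function(m) {
    per_day <- rowMeans(vapply(reports[[m]], `[[`, numeric(7),
                               "per_day_ape"))
    c(per_day, Overall = mean(per_day), Workday = mean(per_day[1:5]),
      Weekend = mean(per_day[6:7]))
  }, numeric(10)))
  structure(list(reports = reports, pooled = pooled, weights = w1,
                 test_weeks = first_test:n_weeks),
            class = "rolling_eval")
}

#' @export
print.rolling_eval <- function(x, ...) {
  cat("Rolling one-week-ahead evaluation over ", length(x$test_weeks),
      " test weeks (weeks ", x$test_weeks[1L], "-",
      x$test_weeks[length(x$test_weeks)], ")\n", sep = "")
  cat("mean absolute percentage errors, averaged across test weeks (%):\n")
  print(round(x$pooled, 2))
  cat("per-origin ARIMA weight w1: ",
      paste(round(x$weights, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}
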