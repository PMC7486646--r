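#' Bundled worked-example week
#'
#' A fixed reference week used throughout the documentation and tests: one
#' week of observed daily outpatient blood-collection counts (Monday to
#' Sunday) together with the one-week-ahead predictions of the two
#' component models for that week, the combination weights `(0.73, 0.27)`,
#' and the per-weekday smoothing constants that produced the SES row.  The
#' counts show the canonical shape of blood-sampling demand — a Monday
#' peak near 5400 falling to a Sunday trough near 750.
#'
#' Because the rows are stored values, everything derived from them
#' (combined forecasts, percentage errors, weekly summaries) is exactly
#' reproducible with no external data; see [reproduce_example_week()].
#'
#' @return list with numeric length-7 vectors `observed`, `arima`, `ses`
#'   (Monday first), `weights` (`w1`, `w2`) and `alphas`.
#' @export
example_week <- function() {
  list(
    observed = stats::setNames(
      c(5387, 5155, 5095, 4862, 4003, 2401, 755), WEEKDAYS),
    arima = stats::setNames(
      c(5337, 5147, 5091, 4997, 4034, 2369, 625), WEEKDAYS),
    ses = stats::setNames(
      c(5377, 5191, 5120, 4954, 3918, 2313, 627), WEEKDAYS),
    weights = c(w1 = 0.73, w2 = 0.27),
    alphas = stats::setNames(
      c(0.099, 0.200, 0.006, 0.100, 0.003, 0.027, 0.199), WEEKDAYS)
  )
}

#' Score the worked-example week end to end
#'
#' Combines the example week's two component prediction rows with its
#' stored weights and scores all three forecasts against the observed row:
#' per-day absolute percentage errors, overall, workday (Mon-Fri) and
#' weekend (Sat-Sun) means, all computed from exact (unrounded)
#' arithmetic.  Needs no external data.
#'
#' @return object of class `example_week_report`: list with `reports`
#'   (named list of [week_report()]s for `arima`, `ses`, `combined`),
#'   `combined` (the combined forecast vector), `weights`, and `table`,
#'   a matrix of percentages with columns Mon..Sun, Overall, Workday,
#'   Weekend.
#' @examples
#' reproduce_example_week()
#' @export
reproduce_example_week <- function() {
  ex <- example_week()
  comb <- combine_forecasts(ex$arima, ex$ses,
                            manual_weights(ex$weights[["w1"]]))
  reports <- list(arima = week_report(ex$observed, ex$arima),
                  ses = week_report(ex$observed, ex$ses),
                  combined = week_report(ex$observed, comb$combined))
  table <- t(vapply(reports, function(r)
    c(r$per_day_ape, Overall = r$overall_mape, Workday = r$workday_mape,
      Weekend = r$weekend_mape), numeric(10)))
  structure(list(reports = reports, combined = comb$combined,
                 weights = ex$weights, table = table),
            class = "example_week_report")
}

#' @export
print.example_week_report <- function(x, ...) {
  cat("Worked-example week: absolute percentage errors (%)\n")
  print(round(x$table, 2))
  cat("combined forecast (w1 = ", x$weights[["w1"]], ", w2 = ",
      x$weights[["w2"]], "):\n", sep = "")
  print(round(x$combined, 2))
  cat("signed combined residuals (counts):\n")
  print(round(x$reports$combined$residuals))
  cat("Note: workday and weekend columns are unweighted means of the\n",
      "per-day percentage errors.\n", sep = "")
  invisible(x)
}
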