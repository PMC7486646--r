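#' Mean absolute percentage error
#'
#' `100 / N * sum(|Y_t - Yhat_t| / Y_t)`, in percent.  All observed values
#' must be strictly positive (daily visit counts are); a zero observation
#' makes the measure undefined and is an error.
#'
#' @param observed,predicted aligned numeric vectors.
#' @return MAPE in percent (scalar).
#' @examples
#' mape(c(100, 200), c(110, 180))   # 10
#' @export
mape <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' differ in length")
  if (length(observed) == 0L) stop("empty input")
  if (any(observed <= 0))
    stop("MAPE undefined: observed values must be strictly positive")
  100 * mean(abs(observed - predicted) / observed)
}

#' Score one forecast week day by day
#'
#' Computes the seven absolute percentage errors (Monday first), their
#' overall mean, the workday (Mon-Fri) mean, the weekend (Sat-Sun) mean,
#' and the signed count residuals.  All summaries are unweighted arithmetic
#' means of per-day percentage errors; nothing is rounded internally (the
#' print method rounds percentages to 2 decimals and residuals to whole
#' counts).
#'
#' @param observed,predicted numeric vectors of exactly 7 values, Monday
#'   first.
#' @return object of class `week_report`: list with `per_day_ape` (named,
#'   percent), `overall_mape`, `workday_mape`, `weekend_mape`, `residuals`
#'   (observed minus predicted), `n`.
#' @export
week_report <- function(observed, predicted) {
  if (length(observed) != 7L || length(predicted) != 7L)
    stop("a week report needs exactly 7 observed and 7 predicted values")
  if (any(observed <= 0))
    stop("observed counts must be strictly positive")
  ape <- 100 * abs(observed - predicted) / observed
  names(ape) <- WEEKDAYS
  structure(list(per_day_ape = ape,
                 overall_mape = mean(ape),
                 workday_mape = mean(ape[1:5]),
                 weekend_mape = mean(ape[6:7]),
                 residuals = stats::setNames(observed - predicted, WEEKDAYS),
                 n = 7L),
            class = "week_report")
}

#' @export
print.week_report <- function(x, ...) {
  tab <- c(round(x$per_day_ape, 2),
           Overall = round(x$overall_mape, 2),
           Workday = round(x$workday_mape, 2),
           Weekend = round(x$weekend_mape, 2))
  print(tab)
  cat("signed residuals (counts):\n")
  print(round(x$residuals))
  invisible(x)
}
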