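#' Initial level for per-weekday exponential smoothing
#'
#' The mean of the first three weeks' observations of the weekday series,
#' used as the starting smoothed value.
#'
#' @param x numeric vector: one weekday's counts across weeks.
#' @return the arithmetic mean of the first three values.
#' @export
ses_init_level <- function(x) {
  if (length(x) < 3L)
    stop("need at least 3 weeks to initialise the level, got ", length(x))
  mean(x[1:3])
}

#' Simple exponential smoothing of one weekday's series
#'
#' Runs the recursion `S_{w+1} = alpha * y_w + (1 - alpha) * S_w` with
#' `S_1 = initial_level`; `S_w` is the one-step-ahead prediction of week
#' `w`, and `S_{n+1}` is the next-week forecast.  In-sample one-step errors
#' for scoring start at week 4, after the three-week initialisation window,
#' so the initial level does not dominate the error criterion.
#'
#' @param x numeric vector of one weekday's counts across weeks.
#' @param alpha smoothing constant, strictly inside (0, 1).
#' @param initial_level starting smoothed value; defaults to
#'   [ses_init_level()] of `x`.
#' @param weekday optional weekday index 1..7, carried through for
#'   reporting.
#' @return object of class `ses_fit`: `weekday`, `alpha`, `initial_level`,
#'   `smoothed` (predictions of weeks 1..n), `forecast_next`,
#'   `in_sample_mse` and `in_sample_mape` (weeks 4..n).
#' @examples
#' ses_smooth(c(10, 12), alpha = 0.5, initial_level = 10)$forecast_next  # 11
#' @export
ses_smooth <- function(x, alpha, initial_level = ses_init_level(x),
                       weekday = NA_integer_) {
  if (length(x) == 0L) stop("empty series")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1), got ", alpha)
  n <- length(x)
  s <- numeric(n + 1L)
  s[1L] <- initial_level
  for (w in seq_len(n)) s[w + 1L] <- alpha * x[w] + (1 - alpha) * s[w]
  smoothed <- s[seq_len(n)]
  score <- if (n >= 4L) 4:n else integer()
  err <- x[score] - smoothed[score]
  structure(list(weekday = weekday, alpha = alpha,
                 initial_level = initial_level, smoothed = smoothed,
                 forecast_next = s[n + 1L],
                 in_sample_mse = if (length(err)) mean(err^2) else NA_real_,
                 in_sample_mape = if (length(err))
                   100 * mean(abs(err) / x[score]) else NA_real_),
            class = "ses_fit")
}

#' @export
print.ses_fit <- function(x, ...) {
  cat("SES fit", if (!is.na(x$weekday)) paste0(" (", WEEKDAYS[x$weekday], ")"),
      ": alpha = ", format(x$alpha), ", initial level = ",
      round(x$initial_level, 2), "\n", sep = "")
  cat("next-week forecast ", round(x$forecast_next, 2),
      ", in-sample MSE ", format(x$in_sample_mse, digits = 5),
      ", MAPE ", round(x$in_sample_mape, 2), "%\n", sep = "")
  invisible(x)
}

#' Choose the smoothing constant on a grid
#'
#' Evaluates the one-step in-sample error of [ses_smooth()] at every grid
#' value and returns the minimiser; ties break toward the smaller alpha.
#' The default grid (0.001 to 0.999 in steps of 0.001) resolves smoothing
#' constants to three decimals.  The objective is the mean squared error by
#' default; mean absolute percentage error is available as an alternative.
#'
#' @inheritParams ses_smooth
#' @param grid candidate alphas, all strictly inside (0, 1).
#' @param objective `"mse"` (default) or `"mape"`.
#' @return the selected alpha (scalar).
#' @export
select_alpha <- function(x, grid = seq(0.001, 0.999, by = 0.001),
                         objective = c("mse", "mape"),
                         initial_level = ses_init_level(x)) {
  objective <- match.arg(objective)
  if (length(grid) == 0L) stop("empty alpha grid")
  if (any(grid <= 0 | grid >= 1))
    stop("alpha grid values must lie strictly inside (0, 1)")
  grid <- sort(grid)
  n <- length(x)
  if (n < 4L)
    stop("need at least 4 weeks (3 to initialise + 1 to score), got ", n)
  # recursion vectorised over the grid: one length-|grid| state vector
  s <- rep(initial_level, length(grid))
  obj <- numeric(length(grid))
  for (w in seq_len(n)) {
    if (w >= 4L) {
      e <- x[w] - s
      obj <- obj + if (objective == "mse") e^2 else abs(e) / x[w]
    }
    s <- grid * x[w] + (1 - grid) * s
  }
  grid[which.min(obj)]   # ascending grid: ties -> smaller alpha
}

#' Per-weekday exponential smoothing forecasts for the next week
#'
#' Fits one simple-exponential-smoothing model to each weekday's values
#' across weeks and returns the seven next-week forecasts.  With
#' `alphas = "auto"` the smoothing constant is selected independently per
#' weekday by [select_alpha()]; alternatively supply seven manual values
#' (Monday first).
#'
#' @param panel a `weekday_panel` with at least 4 weeks.
#' @param alphas `"auto"` or a numeric vector of 7 smoothing constants.
#' @param grid,objective passed to [select_alpha()] when `alphas = "auto"`.
#' @return object of class `ses_panel_fit`: list with `fits` (seven
#'   `ses_fit` objects), `alphas`, and `forecast` (named length-7 vector).
#' @export
forecast_ses <- function(panel, alphas = "auto",
                         grid = seq(0.001, 0.999, by = 0.001),
                         objective = c("mse", "mape")) {
  stopifnot(inherits(panel, "weekday_panel"))
  objective <- match.arg(objective)
  if (nrow(panel) < 4L)
    stop("need at least 4 weeks (3 to initialise + 1 to smooth), got ",
         nrow(panel))
  auto <- identical(alphas, "auto")
  if (!auto && length(alphas) != 7L)
    stop("'alphas' must be \"auto\" or exactly 7 values (Mon..Sun)")
  fits <- lapply(1:7, function(tau) {
    x <- panel[, tau]
    a <- if (auto) select_alpha(x, grid = grid, objective = objective) else
      alphas[tau]
    ses_smooth(x, alpha = a, weekday = tau)
  })
  fc <- vapply(fits, `[[`, numeric(1), "forecast_next")
  names(fc) <- WEEKDAYS
  structure(list(fits = fits,
                 alphas = stats::setNames(
                   vapply(fits, `[[`, numeric(1), "alpha"), WEEKDAYS),
                 forecast = fc),
            class = "ses_panel_fit")
}

#' @export
print.ses_panel_fit <- function(x, ...) {
  cat("Per-weekday simple exponential smoothing\n")
  tab <- rbind(alpha = x$alphas, forecast = round(x$forecast, 1))
  print(tab)
  invisible(x)
}
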