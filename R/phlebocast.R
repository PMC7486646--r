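#' Fit the hybrid ARIMA + per-weekday SES demand model
#'
#' Fits both components of the combined forecasting model to a daily count
#' series and estimates the residual-correction combination weights:
#'
#' * an ARIMA component — the series is differenced (`d` regular passes
#'   plus `D` weekly seasonal passes at lag `s = 7`) and a pure
#'   moving-average model of order `q` is fitted to the remainder by
#'   conditional least squares ([fit_ma()]);
#' * an SES component — one simple-exponential-smoothing model per weekday
#'   across weeks, initialised from the first three weeks, with the
#'   smoothing constant selected per weekday on a fine grid
#'   ([forecast_ses()]);
#' * combination weights estimated from the aligned in-sample one-step
#'   residuals of the two components ([estimate_weights()]), so the
#'   convex combination `w1 * arima + w2 * ses` corrects each model with
#'   the other.
#'
#' The series is trimmed to whole Monday-to-Sunday weeks first; set
#' `preprocess = TRUE` to also replace per-weekday 2-SD singularities by
#' neighbour averages before fitting.
#'
#' @param x a `daily_counts` object, or a data frame with columns `date`
#'   and `count`.
#' @param d,D,s differencing specification (regular order, seasonal order,
#'   period); defaults `1, 1, 7`.
#' @param q moving-average order (default 7, one coefficient per weekday
#'   lag); ignored when `q_candidates` is given.
#' @param q_candidates optional integer vector of orders to compare by BIC
#'   via [select_order()].
#' @param alpha `"auto"` (per-weekday grid selection) or 7 manual
#'   smoothing constants, Monday first.
#' @param alpha_grid,alpha_objective passed to [select_alpha()].
#' @param weight_method passed to [estimate_weights()].
#' @param weights optional `comb_weights` object (e.g. [manual_weights()]);
#'   overrides estimation.
#' @param log_transform fit the ARIMA component on the log scale
#'   (forecasts are transformed back to counts); default off.
#' @param preprocess replace 2-SD singularities before fitting.
#' @param sd_mult,neighbours singularity rule parameters, see
#'   [preprocess_series()].
#' @return object of class `phlebocast`; see [predict.phlebocast()],
#'   [summary.phlebocast()], [residuals.phlebocast()].
#' @examples
#' fit <- phlebocast(simulate_counts(sim_config(n_weeks = 20), seed = 1))
#' predict(fit)
#' @export
phlebocast <- function(x, d = 1L, D = 1L, s = 7L,
                       q = 7L, q_candidates = NULL,
                       alpha = "auto",
                       alpha_grid = seq(0.001, 0.999, by = 0.001),
                       alpha_objective = c("mse", "mape"),
                       weight_method = c("cls", "inverse-error",
                                         "bates-granger"),
                       weights = NULL,
                       log_transform = FALSE,
                       preprocess = FALSE, sd_mult = 2,
                       neighbours = c("adjacent", "preceding")) {
  cl <- match.call()
  alpha_objective <- match.arg(alpha_objective)
  weight_method <- match.arg(weight_method)
  neighbours <- match.arg(neighbours)
  if (!inherits(x, "daily_counts")) x <- daily_counts(x$date, x$count)
  x <- trim_to_whole_weeks(x)
  replacements <- NULL
  if (preprocess) {
    pre <- preprocess_series(x, sd_mult = sd_mult, neighbours = neighbours)
    x <- pre$series
    replacements <- pre$replacements
  }
  n <- nrow(x)
  n_weeks <- n %/% 7L
  y <- x$count
  if (log_transform && any(y <= 0))
    stop("log transform needs strictly positive counts")
  z <- if (log_transform) log(y) else y

  # ARIMA component
  w <- difference(z, d = d, D = D, s = s)
  ma_fit <- if (is.null(q_candidates)) fit_ma(w, q) else
    select_order(w, q_candidates)
  burn <- d + D * s
  fitted_work <- z[(burn + 1L):n] - ma_fit$residuals
  fitted_arima <- c(rep(NA_real_, burn),
                    if (log_transform) exp(fitted_work) else fitted_work)
  fc_work <- forecast_arima(z, ma_fit, d = d, D = D, s = s, horizon = 7L)
  fc_arima <- if (log_transform) exp(fc_work) else fc_work

  # SES component (always on the count scale)
  panel <- to_panel(x)
  ses_fit <- forecast_ses(panel, alphas = alpha, grid = alpha_grid,
                          objective = alpha_objective)
  ses_daily <- as.numeric(t(vapply(ses_fit$fits, `[[`,
                                   numeric(n_weeks), "smoothed")))
  # ses_daily[t] is the one-step prediction of day t (week of t, weekday of t)

  # combination weights from aligned in-sample one-step residuals:
  # days past the differencing burn-in and past the 3-week SES window
  t_all <- seq_len(n)
  window <- t_all[t_all > burn & ((t_all - 1L) %/% 7L) + 1L >= 4L]
  e1 <- y[window] - fitted_arima[window]
  e2 <- y[window] - ses_daily[window]
  if (is.null(weights))
    weights <- estimate_weights(e1, e2, method = weight_method,
                                observed = y[window])
  stopifnot(inherits(weights, "comb_weights"))
  forecast <- combine_forecasts(fc_arima, ses_fit$forecast, weights)

  structure(list(series = x, n_weeks = n_weeks,
                 spec = list(d = d, D = D, s = s),
                 log_transform = log_transform,
                 ma_fit = ma_fit, ses_fit = ses_fit,
                 fitted_arima = fitted_arima, fitted_ses = ses_daily,
                 weights = weights, forecast = forecast,
                 forecast_dates = x$date[n] + 1:7,
                 window = window, replacements = replacements,
                 call = cl),
            class = "phlebocast")
}

#' @export
print.phlebocast <- function(x, ...) {
  cat("Hybrid ARIMA + per-weekday SES forecast model\n")
  cat("series: ", x$n_weeks, " whole weeks (", format(x$series$date[1L]),
      " to ", format(x$series$date[nrow(x$series)]), ")\n", sep = "")
  cat("ARIMA component: MA(", x$ma_fit$q, ") after differencing (d = ",
      x$spec$d, ", D = ", x$spec$D, ", s = ", x$spec$s, "), BIC = ",
      format(x$ma_fit$bic, digits = 6), "\n", sep = "")
  cat("SES component: alpha =",
      paste(format(x$ses_fit$alphas), collapse = " "), "\n")
  cat("weights (", x$weights$method, "): w1 = ",
      round(x$weights$w1, 3), ", w2 = ", round(x$weights$w2, 3),
      "\n", sep = "")
  cat("next-week combined forecast:\n")
  print(round(stats::setNames(x$forecast$combined, WEEKDAYS), 1))
  invisible(x)
}

#' Predictions from a fitted hybrid model
#'
#' Returns the next-week (7-day) forecasts on the count scale.
#'
#' @param object a `phlebocast` fit.
#' @param model `"combined"` (default), `"arima"`, `"ses"`, or `"all"` for
#'   a data frame with the dates and all three.
#' @param ... unused.
#' @return a named length-7 vector, or a data frame when `model = "all"`.
#' @export
predict.phlebocast <- function(object,
                               model = c("combined", "arima", "ses", "all"),
                               ...) {
  model <- match.arg(model)
  fc <- object$forecast
  if (model == "all")
    return(data.frame(date = object$forecast_dates, weekday = WEEKDAYS,
                      arima = fc$pred1, ses = as.numeric(fc$pred2),
                      combined = fc$combined))
  stats::setNames(
    as.numeric(switch(model, combined = fc$combined, arima = fc$pred1,
                      ses = fc$pred2)),
    WEEKDAYS)
}

#' In-sample one-step residuals of a fitted hybrid model
#'
#' Residuals (observed minus one-step prediction) over the aligned
#' in-sample window used for weight estimation: days past both the
#' differencing burn-in and the three-week SES initialisation.
#'
#' @param object a `phlebocast` fit.
#' @param model `"combined"` (default), `"arima"` or `"ses"`.
#' @param ... unused.
#' @return numeric vector, one value per window day.
#' @export
residuals.phlebocast <- function(object,
                                 model = c("combined", "arima", "ses"),
                                 ...) {
  model <- match.arg(model)
  y <- object$series$count
  w <- object$window
  e1 <- y[w] - object$fitted_arima[w]
  e2 <- y[w] - object$fitted_ses[w]
  switch(model,
         arima = e1, ses = e2,
         combined = object$weights$w1 * e1 + object$weights$w2 * e2)
}

#' @export
fitted.phlebocast <- function(object,
                              model = c("combined", "arima", "ses"), ...) {
  model <- match.arg(model)
  object$series$count[object$window] -
    residuals(object, model = model)
}

#' @export
coef.phlebocast <- function(object, ...) {
  c(object$ma_fit$theta,
    stats::setNames(object$ses_fit$alphas, paste0("alpha_", WEEKDAYS)),
    w1 = object$weights$w1, w2 = object$weights$w2)
}

#' Summary of a fitted hybrid model
#'
#' Collects the moving-average coefficient table with standard errors and
#' t statistics, the Ljung-Box residual diagnostics (degrees of freedom
#' reduced by the number of fitted MA parameters), the per-weekday
#' smoothing summaries, the combination weights, and the in-sample MAPE of
#' each model over the aligned residual window.
#'
#' @param object a `phlebocast` fit.
#' @param lb_lags lags for the Ljung-Box table.
#' @param ... unused.
#' @return object of class `summary.phlebocast`.
#' @export
summary.phlebocast <- function(object, lb_lags = c(6L, 12L, 18L, 24L, 30L),
                               ...) {
  mf <- object$ma_fit
  coef_table <- data.frame(estimate = mf$theta, se = mf$se,
                           t_value = mf$tstat,
                           p_value = 2 * stats::pnorm(-abs(mf$tstat)))
  lb_lags <- lb_lags[lb_lags < mf$n_obs]
  lb <- suppressWarnings(ljung_box(mf$residuals, lags = lb_lags,
                                   fitdf = mf$q))
  ses_table <- data.frame(
    weekday = WEEKDAYS,
    alpha = as.numeric(object$ses_fit$alphas),
    initial_level = vapply(object$ses_fit$fits, `[[`, numeric(1),
                           "initial_level"),
    mse = vapply(object$ses_fit$fits, `[[`, numeric(1), "in_sample_mse"),
    mape = vapply(object$ses_fit$fits, `[[`, numeric(1), "in_sample_mape"),
    forecast = as.numeric(object$ses_fit$forecast))
  y <- object$series$count[object$window]
  in_mape <- c(arima = mape(y, fitted(object, "arima")),
               ses = mape(y, fitted(object, "ses")),
               combined = mape(y, fitted(object, "combined")))
  structure(list(fit = object, coef_table = coef_table, ljung_box = lb,
                 ses_table = ses_table, in_sample_mape = in_mape),
            class = "summary.phlebocast")
}

#' @export
print.summary.phlebocast <- function(x, ...) {
  print(x$fit)
  cat("\nMoving-average coefficients:\n")
  print(round(x$coef_table, 4))
  cat("\nLjung-Box residual autocorrelation (fitdf = ", x$fit$ma_fit$q,
      "):\n", sep = "")
  print(transform(x$ljung_box, statistic = round(statistic, 2),
                  p_value = round(p_value, 4)), row.names = FALSE)
  cat("\nPer-weekday exponential smoothing:\n")
  print(transform(x$ses_table, initial_level = round(initial_level, 1),
                  mse = round(mse, 1), mape = round(mape, 2),
                  forecast = round(forecast, 1)), row.names = FALSE)
  cat("\nIn-sample one-step MAPE over the aligned window (%):\n")
  print(round(x$in_sample_mape, 2))
  invisible(x)
}

#' Plot a fitted hybrid model
#'
#' Observed series with the combined in-sample one-step fit overlaid and
#' the next-week component and combined forecasts beyond the sample end.
#'
#' @param x a `phlebocast` fit.
#' @param ... passed to [plot.default()].
#' @export
plot.phlebocast <- function(x, ...) {
  s <- x$series
  fd <- x$forecast_dates
  plot(s$date, s$count, type = "l", col = "grey40",
       xlab = "date", ylab = "daily count",
       xlim = range(c(s$date, fd)), ...)
  graphics::lines(s$date[x$window], fitted(x, "combined"), col = "steelblue")
  graphics::points(fd, x$forecast$pred1, col = "darkorange", pch = 2)
  graphics::points(fd, x$forecast$pred2, col = "forestgreen", pch = 6)
  graphics::points(fd, x$forecast$combined, col = "firebrick", pch = 19)
  graphics::legend("topleft",
                   legend = c("observed", "combined fit", "ARIMA fc",
                              "SES fc", "combined fc"),
                   col = c("grey40", "steelblue", "darkorange",
                           "forestgreen", "firebrick"),
                   lty = c(1, 1, NA, NA, NA), pch = c(NA, NA, 2, 6, 19),
                   bty = "n", cex = 0.8)
  invisible(x)
}
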