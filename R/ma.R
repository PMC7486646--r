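#' Fit a pure moving-average model by conditional least squares
#'
#' Fits `x_t = e_t - theta_1 e_{t-1} - ... - theta_q e_{t-q}` to a
#' (differenced, zero-mean) series by minimising the conditional sum of
#' squared innovations, with pre-sample innovations fixed at zero.  The
#' sign convention is `Theta(B) = 1 - theta_1 B - ... - theta_q B^q`, the
#' one most statistical packages print for seasonal count models, so a
#' positive lag-7 coefficient corresponds to a negative lag-7 innovation
#' weight.  Invertibility is enforced by optimising over partial
#' coefficients through a tanh reparameterisation; the fitted polynomial
#' always has all roots outside the unit circle.
#'
#' No mean term is fitted: the model is intended for series that have
#' already been differenced to (approximately) zero mean.
#'
#' @param x numeric series (typically the output of [difference()]).
#' @param q moving-average order, a positive integer.
#' @param maxit iteration cap handed to the BFGS optimiser.
#' @return object of class `ma_css` with components `q`, `theta` (named
#'   ma1..maq), `se`, `tstat`, `sigma2` (SSE / n), `residuals`
#'   (innovations, length `n_obs`), `loglik` (Gaussian), `bic`
#'   (`n log sigma2 + (q + 1) log n`), `n_obs`, and `convergence`.
#' @seealso [select_order()], [ljung_box()], [forecast_arima()]
#' @export
fit_ma <- function(x, q, maxit = 500L) {
  x <- as.numeric(x)
  n <- length(x)
  if (q < 1 || q != round(q)) stop("'q' must be a positive integer")
  if (n <= 3 * q)
    stop("series too short (", n, ") to fit MA(", q, ")")
  css <- function(theta) sum(ma_innovations(x, theta)^2)
  obj <- function(u) css(pacf_to_ma(tanh(u)))
  ctrl <- list(maxit = maxit, reltol = 1e-10)
  opt <- stats::optim(rep(0, q), obj, method = "BFGS", control = ctrl)
  if (opt$convergence != 0)   # one restart from the best point so far
    opt <- stats::optim(opt$par, obj, method = "BFGS", control = ctrl)
  if (opt$convergence != 0)
    stop("conditional least squares did not converge for MA(", q,
         "): optim code ", opt$convergence,
         if (nzchar(opt$message %||% "")) paste0(" (", opt$message, ")"))
  theta <- pacf_to_ma(tanh(opt$par))
  eps <- ma_innovations(x, theta)
  sse <- sum(eps^2)
  sigma2 <- sse / n
  loglik <- -0.5 * n * (log(2 * pi * sigma2) + 1)
  bic <- n * log(sigma2) + (q + 1) * log(n)
  # curvature of the CSS surface in the coefficients themselves
  H <- stats::optimHess(theta, css)
  se <- rep(NA_real_, q)
  cov <- try(2 * sigma2 * solve(H), silent = TRUE)
  if (!inherits(cov, "try-error")) {
    v <- diag(cov)
    se[v > 0] <- sqrt(v[v > 0])
  }
  names(theta) <- names(se) <- paste0("ma", seq_len(q))
  structure(list(q = q, theta = theta, se = se, tstat = theta / se,
                 sigma2 = sigma2, residuals = eps, loglik = loglik,
                 bic = bic, n_obs = n, convergence = opt$convergence),
            class = "ma_css")
}

# innovations of the MA(q) model under Theta(B) = 1 - sum theta_j B^j:
# e_t = x_t + sum_j theta_j e_{t-j}, with e_t = 0 for t <= 0
ma_innovations <- function(x, theta) {
  as.numeric(stats::filter(x, theta, method = "recursive"))
}

# map partial coefficients in (-1, 1) to coefficients of an
# invertible Theta(B) = 1 - theta_1 B - ... - theta_q B^q
# (Levinson-Durbin style recursion, as used for stationary AR regions)
pacf_to_ma <- function(r) {
  th <- r
  q <- length(r)
  if (q > 1) for (k in 2:q)
    th[1:(k - 1)] <- th[1:(k - 1)] - r[k] * th[(k - 1):1]
  th
}

#' @export
print.ma_css <- function(x, ...) {
  cat("MA(", x$q, ") fitted by conditional least squares, n = ", x$n_obs,
      "\n", sep = "")
  tab <- rbind(estimate = x$theta, `s.e.` = x$se)
  print(round(tab, 4))
  cat("sigma^2 = ", format(x$sigma2, digits = 6),
      ",  log-likelihood = ", format(x$loglik, digits = 6),
      ",  BIC = ", format(x$bic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ma_css <- function(object, ...) object$theta

#' @export
residuals.ma_css <- function(object, ...) object$residuals

#' Forecast an MA(q) fit on its own (differenced) scale
#'
#' Conditional expectations with future innovations set to zero:
#' `xhat_{n+h} = -sum_{j >= h} theta_j e_{n+h-j}`.  Beyond lag `q` the
#' forecasts are exactly zero — a moving-average model has finite memory.
#'
#' @param object an `ma_css` fit.
#' @param h forecast horizon.
#' @param ... unused.
#' @return numeric vector of `h` forecasts.
#' @export
predict.ma_css <- function(object, h = 7L, ...) {
  eps <- object$residuals
  n <- length(eps)
  theta <- object$theta
  vapply(seq_len(h), function(step) {
    j <- seq_len(object$q)
    j <- j[j >= step]           # only in-sample innovations contribute
    if (!length(j)) return(0)
    -sum(theta[j] * eps[n + step - j])
  }, numeric(1))
}

#' Select the moving-average order by BIC
#'
#' Fits each candidate order and returns the fit with the smallest BIC;
#' ties break toward the smaller order.  Candidates whose estimation fails
#' are skipped; if all fail, the per-candidate errors are reported.
#'
#' @param x numeric (differenced) series.
#' @param q_candidates integer vector of orders to try.
#' @return the winning `ma_css` fit, with the BIC table of all successful
#'   candidates attached as attribute `"bic_table"`.
#' @export
select_order <- function(x, q_candidates = 1:7) {
  q_candidates <- sort(unique(as.integer(q_candidates)))
  fits <- vector("list", length(q_candidates))
  errs <- character(length(q_candidates))
  for (i in seq_along(q_candidates)) {
    f <- tryCatch(fit_ma(x, q_candidates[i]), error = function(e) e)
    if (inherits(f, "error")) errs[i] <- conditionMessage(f) else fits[[i]] <- f
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("no candidate order could be fitted:\n",
         paste0("  q = ", q_candidates, ": ", errs, collapse = "\n"))
  bics <- vapply(fits[ok], `[[`, numeric(1), "bic")
  win <- fits[ok][[which.min(bics)]]   # candidates ascending: ties -> smaller q
  attr(win, "bic_table") <- data.frame(q = q_candidates[ok], bic = bics)
  win
}

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' `Q = n (n + 2) sum_{k=1..lag} r_k^2 / (n - k)` with `r_k` the sample
#' autocorrelations of the residuals.  The degrees of freedom at each lag
#' are `lag - fitdf` (the number of fitted moving-average parameters),
#' floored at zero; rows with zero degrees of freedom carry no p-value.
#' With seven fitted parameters, lags (6, 12, 18, 24, 30) therefore give
#' dfs (0, 5, 11, 17, 23).
#'
#' @param residuals numeric residual series.
#' @param lags lags at which to evaluate the statistic.
#' @param fitdf number of parameters estimated in the model whose residuals
#'   are tested.
#' @return data frame with columns `lag`, `statistic`, `df`, `p_value`
#'   (`NA` where `df` is 0).
#' @export
ljung_box <- function(residuals, lags = c(6L, 12L, 18L, 24L, 30L),
                      fitdf = 0L) {
  n <- length(residuals)
  if (max(lags) >= n)
    stop("largest lag (", max(lags), ") must be below the residual length (",
         n, ")")
  r <- stats::acf(residuals, lag.max = max(lags), plot = FALSE,
                  demean = TRUE)$acf[-1L]
  out <- data.frame(lag = as.integer(lags), statistic = NA_real_,
                    df = pmax(as.integer(lags) - as.integer(fitdf), 0L),
                    p_value = NA_real_)
  for (i in seq_along(lags)) {
    k <- seq_len(lags[i])
    out$statistic[i] <- n * (n + 2) * sum(r[k]^2 / (n - k))
    if (out$df[i] > 0L)
      out$p_value[i] <- stats::pchisq(out$statistic[i], out$df[i],
                                      lower.tail = FALSE)
  }
  if (all(out$df == 0L))
    warning("all requested lags are <= fitdf; no p-values available")
  out
}

#' Seven-day level-scale forecast from a differenced MA fit
#'
#' Forecasts the moving-average model on the differenced scale (future
#' innovations zero) and inverts the differencing exactly against the tail
#' of the original series, returning predictions in counts.  The horizon is
#' capped at 7 days, the window over which the pipeline is validated.
#'
#' @param series a `daily_counts` object (or numeric vector) on which
#'   `fit` was built via `difference(series$count, d, D, s)`.
#' @param fit the `ma_css` fit of the differenced series.
#' @param d,D,s the differencing specification used.
#' @param horizon number of days ahead, at most 7.
#' @return numeric vector of `horizon` level-scale forecasts.
#' @export
forecast_arima <- function(series, fit, d = 1L, D = 1L, s = 7L,
                           horizon = 7L) {
  if (horizon > 7L)
    stop("'horizon' is capped at 7 days")
  y <- if (inherits(series, "daily_counts")) series$count else
    as.numeric(series)
  if (length(fit$residuals) != length(y) - d - D * s)
    stop("fit does not match difference(series, d = ", d, ", D = ", D,
         ", s = ", s, "): residual length ", length(fit$residuals),
         " vs expected ", length(y) - d - D * s)
  w_hat <- predict(fit, h = horizon)
  invert_difference(w_hat, utils::tail(y, d + D * s), d = d, D = D, s = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
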