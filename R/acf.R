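#' Sample autocorrelation and partial autocorrelation
#'
#' Thin wrappers used during model identification: `acf_values()` returns
#' the sample autocorrelations r_1..r_max_lag (overall-mean, denominator-n
#' convention of [stats::acf()]), and `pacf_values()` the partial
#' autocorrelations via the Durbin-Levinson recursion underlying
#' [stats::pacf()].  A weekly-periodic series shows its period as a peak
#' at lag 7; strong decay only after differencing indicates the
#' differencing specification is doing its job.
#'
#' @param x numeric series; must not be constant (autocorrelation is then
#'   undefined).
#' @param max_lag largest lag, below `length(x)`.
#' @return numeric vector of `max_lag` values (lags 1..max_lag).
#' @export
acf_values <- function(x, max_lag) {
  check_acf_input(x, max_lag)
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf[-1L])
}

#' @rdname acf_values
#' @export
pacf_values <- function(x, max_lag) {
  check_acf_input(x, max_lag)
  as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE)$acf)
}

check_acf_input <- function(x, max_lag) {
  if (max_lag >= length(x))
    stop("'max_lag' must be below the series length")
  if (stats::var(x) == 0)
    stop("autocorrelation undefined for a constant series")
  invisible(NULL)
}
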