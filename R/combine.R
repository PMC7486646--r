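#' Estimate residual-correction combination weights
#'
#' Given aligned one-step residuals of the two component models over the
#' same fitting window, chooses convex weights `(w1, w2)`, `w1 + w2 = 1`,
#' for the combined forecast.  The default, `"cls"`, is constrained least
#' squares: minimise `sum((w1 * e1 + w2 * e2)^2)` subject to `w1 + w2 = 1`,
#' then clip to `[0, 1]` and renormalise.  Alternatives: `"inverse-error"`
#' (weights proportional to the reciprocal in-window MAPE of each model,
#' which needs `observed`) and `"bates-granger"` (the classical
#' minimum-variance formula from uncentred second moments,
#' `w1 = (s2^2 - s12) / (s1^2 + s2^2 - 2 s12)`, reported unclipped).
#'
#' Degenerate cases: a model with all-zero residuals receives full weight;
#' identical residual vectors make the objective flat and return
#' `(0.5, 0.5)` with a warning.
#'
#' @param e1 residuals (observed minus predicted) of the first model,
#'   conventionally the ARIMA component.
#' @param e2 residuals of the second model (the SES component), same
#'   length and alignment as `e1`.
#' @param method `"cls"`, `"inverse-error"` or `"bates-granger"`.
#' @param observed observed counts over the window; required for
#'   `"inverse-error"`.
#' @return object of class `comb_weights`: list with `w1`, `w2`, `method`,
#'   `n` (window length).
#' @export
estimate_weights <- function(e1, e2,
                             method = c("cls", "inverse-error",
                                        "bates-granger"),
                             observed = NULL) {
  method <- match.arg(method)
  if (length(e1) == 0L || length(e1) != length(e2))
    stop("residual vectors must be non-empty and of equal length")
  if (isTRUE(all.equal(e1, e2, tolerance = 1e-12)) && any(e1 != 0)) {
    warning("identical residual vectors: combination objective is flat, ",
            "returning equal weights")
    return(new_weights(0.5, method, length(e1)))
  }
  w1 <- switch(method,
    cls = {
      d <- e1 - e2
      if (all(d == 0)) 0.5 else min(1, max(0, -sum(e2 * d) / sum(d^2)))
    },
    `bates-granger` = {
      s1 <- mean(e1^2); s2 <- mean(e2^2); s12 <- mean(e1 * e2)
      den <- s1 + s2 - 2 * s12
      if (den == 0) 0.5 else (s2 - s12) / den
    },
    `inverse-error` = {
      if (is.null(observed))
        stop("method \"inverse-error\" needs 'observed' to compute MAPE")
      if (length(observed) != length(e1) || any(observed <= 0))
        stop("'observed' must align with the residuals and be positive")
      m1 <- mean(abs(e1) / observed)
      m2 <- mean(abs(e2) / observed)
      if (m1 == 0 && m2 == 0) 0.5
      else if (m1 == 0) 1
      else if (m2 == 0) 0
      else (1 / m1) / (1 / m1 + 1 / m2)
    })
  new_weights(w1, method, length(e1))
}

new_weights <- function(w1, method, n) {
  structure(list(w1 = w1, w2 = 1 - w1, method = method, n = n),
            class = "comb_weights")
}

#' Manually specified combination weights
#'
#' Wraps externally chosen weights (for instance a published pair such as
#' 0.73 / 0.27) in the object [combine_forecasts()] expects.
#'
#' @param w1 weight of the first (ARIMA) component.
#' @param w2 weight of the second (SES) component; must satisfy
#'   `w1 + w2 = 1`.
#' @return a `comb_weights` object with method `"manual"`.
#' @export
manual_weights <- function(w1, w2 = 1 - w1) {
  if (abs(w1 + w2 - 1) > 1e-8) stop("weights must sum to 1")
  new_weights(w1, "manual", 0L)
}

#' @export
print.comb_weights <- function(x, ...) {
  cat("Combination weights (", x$method, "): w1 = ", format(x$w1),
      ", w2 = ", format(x$w2),
      if (x$n > 0) paste0("  [window n = ", x$n, "]"), "\n", sep = "")
  invisible(x)
}

#' Convex combination of two component forecasts
#'
#' Elementwise `w1 * pred1 + w2 * pred2`.  No rounding is applied; display
#' layers round.  With weights in `[0, 1]` every combined value lies
#' between the two component values.
#'
#' @param pred1,pred2 aligned numeric forecast vectors (typically 7 days,
#'   Monday first) from the ARIMA and SES components.
#' @param weights a `comb_weights` object (from [estimate_weights()] or
#'   [manual_weights()]).
#' @return object of class `combined_forecast`: list with `combined`,
#'   `pred1`, `pred2`, `weights`.
#' @export
combine_forecasts <- function(pred1, pred2, weights) {
  stopifnot(inherits(weights, "comb_weights"))
  if (length(pred1) != length(pred2))
    stop("component forecasts differ in length (", length(pred1), " vs ",
         length(pred2), ")")
  structure(list(combined = weights$w1 * pred1 + weights$w2 * pred2,
                 pred1 = pred1, pred2 = pred2, weights = weights),
            class = "combined_forecast")
}

#' @export
print.combined_forecast <- function(x, ...) {
  print(x$weights)
  tab <- rbind(arima = x$pred1, ses = x$pred2, combined = x$combined)
  print(round(tab, 2))
  invisible(x)
}
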