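#' Regular and seasonal differencing
#'
#' `difference()` applies `d` regular (lag-1) differences followed by `D`
#' seasonal differences at lag `s` (the two operators commute).  With the
#' package default `d = 1, D = 1, s = 7` — one regular pass plus one weekly
#' seasonal pass — a linear trend and any fixed weekly profile are removed
#' exactly, which is what makes a short moving-average model adequate for
#' the remainder.
#'
#' @param x numeric series.
#' @param d number of regular differences (non-negative integer).
#' @param D number of seasonal differences (non-negative integer).
#' @param s seasonal period in days; 7 throughout this package.
#' @return numeric vector of length `length(x) - d - D * s`.
#' @examples
#' difference(c(1, 3, 6, 10), d = 1, D = 0)   # 2 3 4
#' @export
difference <- function(x, d = 1L, D = 1L, s = 7L) {
  stopifnot(d >= 0, D >= 0, s >= 1)
  if (length(x) <= d + D * s)
    stop("series of length ", length(x), " is too short for d = ", d,
         ", D = ", D, ", s = ", s)
  if (d > 0) x <- diff(x, lag = 1L, differences = d)
  if (D > 0) x <- diff(x, lag = s, differences = D)
  x
}

#' Invert differencing to return forecasts to the level scale
#'
#' Exact left inverse of [difference()]: given future values on the
#' differenced scale and the tail of the original series, reconstructs the
#' future values on the level scale by undoing the seasonal passes first
#' and the regular passes last.  `history` must supply at least the last
#' `d + D * s` original values.
#'
#' @param w future values on the differenced scale.
#' @param history tail of the original (undifferenced) series.
#' @inheritParams difference
#' @return numeric vector of `length(w)` level-scale values.
#' @export
invert_difference <- function(w, history, d = 1L, D = 1L, s = 7L) {
  stopifnot(d >= 0, D >= 0, s >= 1)
  need <- d + D * s
  if (length(history) < need)
    stop("need at least ", need, " historical values, got ", length(history))
  # histories on each partially differenced scale: after i regular passes
  reg <- vector("list", d + 1L)
  reg[[1L]] <- history
  if (d > 0) for (i in seq_len(d)) reg[[i + 1L]] <- diff(reg[[i]])
  sea <- vector("list", D + 1L)
  sea[[1L]] <- reg[[d + 1L]]
  if (D > 0) for (j in seq_len(D)) sea[[j + 1L]] <- diff(sea[[j]], lag = s)
  # undo seasonal passes (innermost first), then regular passes
  if (D > 0) for (j in D:1L) w <- undiff(w, sea[[j]], s)
  if (d > 0) for (i in d:1L) w <- undiff(w, reg[[i]], 1L)
  w
}

# cumulative inversion of one differencing pass at the given lag
undiff <- function(w, hist, lag) {
  out <- numeric(length(w))
  nh <- length(hist)
  for (k in seq_along(w)) {
    prev <- if (k > lag) out[k - lag] else hist[nh - lag + k]
    out[k] <- w[k] + prev
  }
  out
}
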