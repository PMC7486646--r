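#' Generator configuration for synthetic daily blood-collection counts
#'
#' Bundles and validates the parameters of the synthetic series generator.
#' The defaults are calibrated so that a long simulated series has a
#' long-run mean of about 3950 visits per day and a standard deviation of
#' about 1700, with the weekday shape typical of outpatient blood-sampling
#' demand: a Monday peak, a mild decline through the working week, a low
#' Saturday and a far lower Sunday.  All default values are synthetic
#' package choices, not measurements.
#'
#' @param n_weeks number of whole Monday-to-Sunday weeks to generate.
#' @param base_level mean weekday count before the weekday profile, trend
#'   and seasonality are applied (counts).
#' @param weekday_profile 7 non-negative multipliers, Monday first.
#' @param annual_amplitude amplitude of the annual sinusoid as a fraction of
#'   the local level (>= 0); the period is 364 days (52 whole weeks) so the
#'   annual and weekly cycles commute with whole-week trimming.
#' @param trend_slope linear drift in counts per day (may be negative).
#' @param noise_sd standard deviation of additive Gaussian noise (counts).
#' @param holiday_rate probability, per day, of a holiday-style depression.
#' @param holiday_factor multiplier in \[0, 1\] applied on holiday days.
#' @param start Monday on which the series starts.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_weeks = 60L,
                       base_level = 3880,
                       weekday_profile = c(1.36, 1.30, 1.29, 1.23,
                                           1.02, 0.61, 0.19),
                       annual_amplitude = 0.11,
                       trend_slope = 0.5,
                       noise_sd = 200,
                       holiday_rate = 0.02,
                       holiday_factor = 0.35,
                       start = as.Date("2018-01-01")) {
  if (length(n_weeks) != 1L || !is.finite(n_weeks) || n_weeks < 1 ||
      n_weeks != round(n_weeks))
    stop("'n_weeks' must be a positive whole number")
  if (length(weekday_profile) != 7L)
    stop("'weekday_profile' must have exactly 7 entries (Mon..Sun), got ",
         length(weekday_profile))
  if (any(weekday_profile < 0)) stop("'weekday_profile' entries must be >= 0")
  if (annual_amplitude < 0) stop("'annual_amplitude' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (holiday_rate < 0 || holiday_rate > 1)
    stop("'holiday_rate' must lie in [0, 1]")
  if (holiday_factor < 0 || holiday_factor > 1)
    stop("'holiday_factor' must lie in [0, 1]")
  start <- as.Date(start)
  if (as.integer(format(start, "%u")) != 1L)
    stop("'start' must be a Monday")
  structure(list(n_weeks = as.integer(n_weeks), base_level = base_level,
                 weekday_profile = weekday_profile,
                 annual_amplitude = annual_amplitude,
                 trend_slope = trend_slope, noise_sd = noise_sd,
                 holiday_rate = holiday_rate,
                 holiday_factor = holiday_factor, start = start),
            class = "sim_config")
}

#' Deterministic mean function of the generator
#'
#' Expected count on day `t` (1-based from the first Monday) before noise
#' and holiday effects:
#' `(base_level + trend_slope * t) * weekday_profile[tau] *
#'  (1 + annual_amplitude * sin(2 * pi * t / 364))`,
#' where `tau = ((t - 1) mod 7) + 1` is the weekday.
#'
#' @param t integer day index (vectorised).
#' @param config a [sim_config()] object.
#' @return expected counts (not clipped or rounded).
#' @export
expected_counts <- function(t, config = sim_config()) {
  tau <- ((t - 1L) %% 7L) + 1L
  (config$base_level + config$trend_slope * t) *
    config$weekday_profile[tau] *
    (1 + config$annual_amplitude * sin(2 * pi * t / 364))
}

#' Simulate a daily blood-collection count series
#'
#' Draws a dated daily count series with the structure the downstream
#' analysis assumes: a fixed weekday profile, an annual sinusoid, a linear
#' trend, additive Gaussian noise, and occasional holiday days on which the
#' count is multiplicatively depressed.  Counts are clipped at zero and
#' rounded to integers.  Output is reproducible: the same `config` and
#' `seed` give a bit-identical series.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed.
#' @return a [daily_counts()] series of `n_weeks * 7` days starting on a
#'   Monday.
#' @examples
#' s <- simulate_counts(sim_config(n_weeks = 8), seed = 1)
#' mean(s$count)
#' @export
simulate_counts <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_weeks * 7L
  t <- seq_len(n)
  mu <- expected_counts(t, config)
  set.seed(seed)
  x <- mu + stats::rnorm(n, 0, config$noise_sd)
  holiday <- stats::runif(n) < config$holiday_rate
  x[holiday] <- x[holiday] * config$holiday_factor
  daily_counts(seq(config$start, by = "day", length.out = n),
               pmax(0, round(x)))
}

#' Inject per-weekday outliers into a series
#'
#' Perturbs `k` days so that each perturbed value lies beyond `magnitude`
#' sample standard deviations from its weekday's mean (both computed on the
#' input series), giving the singularity detector a known ground truth.
#' Injections are spread over the seven weekday columns (at most
#' `ceiling(k / 7)` per weekday) and their directions alternate within a
#' column, so that injected points do not mask one another by inflating
#' their own column's post-injection spread.  For a weekday column with zero
#' spread the offset falls back to half the column mean (at least 1).
#'
#' @param series a `daily_counts` object (whole weeks, Monday start).
#' @param k number of days to perturb (`k = 0` returns the input unchanged).
#' @param magnitude how many weekday standard deviations to exceed; must be
#'   greater than 2 so injected points trip the 2-SD rule.
#' @param seed integer RNG seed for position choice.
#' @return list with `series` (perturbed) and `positions`, a data frame of
#'   `week`, `day` (weekday index) and `t` (day index) of injected points.
#' @export
inject_singularities <- function(series, k, magnitude = 3, seed = 1L) {
  stopifnot(inherits(series, "daily_counts"))
  n <- nrow(series)
  if (k > n) stop("'k' (", k, ") exceeds series length (", n, ")")
  counts <- series$count
  if (k == 0L)
    return(list(series = series,
                positions = data.frame(week = integer(), day = integer(),
                                       t = integer())))
  if (magnitude <= 2)
    stop("'magnitude' must exceed 2 so injected points trip the 2-SD rule")
  panel <- to_panel(series)
  n_weeks <- nrow(panel)
  set.seed(seed)
  # round-robin over a random weekday order, distinct weeks within a column
  taus <- rep(sample.int(7L), length.out = max(k, 7L))[seq_len(k)]
  week <- integer(k)
  for (tau in unique(taus)) {
    idx <- which(taus == tau)
    week[idx] <- sample.int(n_weeks, length(idx))
  }
  sign_ct <- integer(7L)
  for (i in seq_len(k)) {
    tau <- taus[i]
    col <- panel[, tau]
    s <- stats::sd(col)
    offset <- if (is.finite(s) && s > 0) magnitude * s + 1 else
      max(1, 0.5 * mean(col)) + 1
    sign_ct[tau] <- sign_ct[tau] + 1L
    dir <- if (sign_ct[tau] %% 2L == 0L && mean(col) - offset >= 0) -1 else 1
    t <- 7L * (week[i] - 1L) + tau
    counts[t] <- round(mean(col) + dir * offset)
  }
  pos <- order(7L * (week - 1L) + taus)
  list(series = daily_counts(series$date, counts),
       positions = data.frame(week = week[pos], day = taus[pos],
                              t = (7L * (week - 1L) + taus)[pos]))
}
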