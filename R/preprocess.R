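#' Detect per-weekday singularities
#'
#' A day is a singularity when its count lies outside mean +/- `sd_mult`
#' sample standard deviations of its own weekday's values across weeks
#' (holiday-driven outliers typically trip this rule).  Detection is a
#' single pass: thresholds come from the original columns and are not
#' recomputed after replacements.
#'
#' @param panel a `weekday_panel` from [to_panel()], with at least 3 weeks
#'   so the column standard deviation is meaningful.
#' @param sd_mult threshold in standard deviations (default 2).
#' @return data frame with columns `week`, `day`, `value`, ordered by week
#'   then weekday; zero rows when nothing is flagged.
#' @export
detect_singularities <- function(panel, sd_mult = 2) {
  stopifnot(inherits(panel, "weekday_panel"))
  if (nrow(panel) < 3L)
    stop("need at least 3 weeks to estimate per-weekday spread, got ",
         nrow(panel))
  m <- colMeans(panel)
  s <- apply(panel, 2L, stats::sd)   # sample SD, denominator n - 1
  dev <- abs(sweep(unclass(panel), 2L, m))
  hit <- which(dev > sd_mult * rep(s, each = nrow(panel)), arr.ind = TRUE)
  out <- data.frame(week = as.integer(hit[, 1L]), day = as.integer(hit[, 2L]),
                    value = panel[hit])
  out[order(out$week, out$day), , drop = FALSE]
}

#' Replace flagged singularities by same-weekday neighbour averages
#'
#' Each flagged cell is replaced by the mean of the same weekday's values in
#' the nearest non-flagged earlier week and the nearest non-flagged later
#' week (`neighbours = "adjacent"`, the default).  Cells in a boundary week
#' use the two nearest non-flagged same-weekday values on whichever side
#' exists.  `neighbours = "preceding"` instead averages the two nearest
#' non-flagged earlier weeks (falling back to later weeks when fewer than
#' two exist).
#'
#' @param panel a `weekday_panel`.
#' @param flagged data frame with columns `week` and `day`, as returned by
#'   [detect_singularities()].
#' @param neighbours `"adjacent"` or `"preceding"` (see Details).
#' @return the panel with flagged cells replaced; dimensions unchanged.
#' @export
replace_singularities <- function(panel, flagged,
                                  neighbours = c("adjacent", "preceding")) {
  stopifnot(inherits(panel, "weekday_panel"))
  neighbours <- match.arg(neighbours)
  if (nrow(flagged) == 0L) return(panel)
  if (any(flagged$week < 1L | flagged$week > nrow(panel) |
          flagged$day < 1L | flagged$day > 7L))
    stop("flagged cell outside the panel")
  out <- panel
  for (tau in unique(flagged$day)) {
    bad <- sort(flagged$week[flagged$day == tau])
    good <- setdiff(seq_len(nrow(panel)), bad)
    if (length(good) == 0L)
      stop("every week of weekday ", WEEKDAYS[tau],
           " is flagged; nothing to average")
    for (w in bad) {
      below <- good[good < w]
      above <- good[good > w]
      use <- switch(neighbours,
        adjacent = {
          if (length(below) && length(above))
            c(max(below), min(above))
          else if (length(above)) utils::head(above, 2L)
          else utils::tail(below, 2L)
        },
        preceding = {
          if (length(below) >= 2L) utils::tail(below, 2L)
          else c(below, utils::head(above, 2L - length(below)))
        })
      out[w, tau] <- mean(panel[use, tau])
    }
  }
  out
}

#' Trim, detect and replace singularities in one step
#'
#' Convenience wrapper for the standard cleaning pass: trim the series to
#' whole Monday-to-Sunday weeks, flag per-weekday values beyond `sd_mult`
#' standard deviations, and replace them by same-weekday neighbour
#' averages.
#'
#' @inheritParams detect_singularities
#' @inheritParams replace_singularities
#' @param series a `daily_counts` object.
#' @return list of class `preprocessed` with elements `series` (cleaned),
#'   and `replacements`, a data frame logging `week`, `day`, `date`,
#'   `original` and `replacement` for every edited day.
#' @export
preprocess_series <- function(series, sd_mult = 2,
                              neighbours = c("adjacent", "preceding")) {
  neighbours <- match.arg(neighbours)
  trimmed <- trim_to_whole_weeks(series)
  panel <- to_panel(trimmed)
  flagged <- detect_singularities(panel, sd_mult = sd_mult)
  cleaned <- replace_singularities(panel, flagged, neighbours = neighbours)
  t <- 7L * (flagged$week - 1L) + flagged$day
  log <- data.frame(week = flagged$week, day = flagged$day,
                    date = trimmed$date[t],
                    original = flagged$value,
                    replacement = cleaned[cbind(flagged$week, flagged$day)])
  structure(list(series = from_panel(cleaned), replacements = log),
            class = "preprocessed")
}

#' @export
print.preprocessed <- function(x, ...) {
  print(x$series)
  cat(nrow(x$replacements), "singularit",
      if (nrow(x$replacements) == 1L) "y" else "ies", "replaced\n")
  if (nrow(x$replacements)) print(x$replacements, row.names = FALSE)
  invisible(x)
}
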