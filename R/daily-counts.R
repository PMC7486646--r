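#' Daily count series
#'
#' A `daily_counts` object is a data frame with two columns, `date` (class
#' `Date`, strictly consecutive calendar days) and `count` (non-negative
#' numbers), holding one observation per day.  It is the common currency of
#' the package: the synthetic generator emits one, the preprocessing and
#' fitting functions consume one.
#'
#' @param date vector of class `Date` (or ISO-8601 strings), strictly
#'   increasing by one day.
#' @param count numeric vector of non-negative daily counts, same length as
#'   `date`.
#' @return A data frame of class `daily_counts`.
#' @examples
#' daily_counts(seq(as.Date("2018-01-01"), by = "day", length.out = 14),
#'              rpois(14, 100))
#' @export
daily_counts <- function(date, count) {
  date <- as.Date(date)
  if (anyNA(date)) stop("'date' contains unparseable or missing values")
  count <- as.numeric(count)
  if (length(date) != length(count))
    stop("'date' and 'count' must have the same length")
  if (length(date) == 0L) stop("series is empty")
  validate_daily_counts(structure(
    data.frame(date = date, count = count),
    class = c("daily_counts", "data.frame")
  ))
}

validate_daily_counts <- function(x) {
  d <- diff(as.integer(x$date))
  if (any(d == 0L)) {
    dup <- x$date[which(d == 0L)[1L] + 1L]
    stop("duplicate date: ", format(dup))
  }
  if (any(d != 1L)) {
    i <- which(d > 1L)[1L]
    stop("gap in series: missing ", format(x$date[i] + 1L))
  }
  if (anyNA(x$count)) stop("'count' contains missing values")
  if (any(x$count < 0)) {
    i <- which(x$count < 0)[1L]
    stop("negative count at row ", i, " (", format(x$date[i]), ")")
  }
  x
}

#' @export
print.daily_counts <- function(x, ...) {
  cat("Daily count series: ", nrow(x), " days (",
      format(x$date[1L]), " to ", format(x$date[nrow(x)]), ")\n", sep = "")
  cat("mean ", round(mean(x$count), 1), ", sd ", round(stats::sd(x$count), 2),
      "\n", sep = "")
  invisible(x)
}

#' Weekday index of each date
#'
#' ISO convention: Monday = 1, ..., Sunday = 7.
#' @param x a `daily_counts` object or a `Date` vector.
#' @return integer vector in 1..7.
#' @export
weekday_index <- function(x) {
  if (inherits(x, "daily_counts")) x <- x$date
  as.integer(format(as.Date(x), "%u"))
}

#' Read or write a daily count series as CSV
#'
#' The file format is a two-column CSV with header `date,count`, ISO-8601
#' dates, one row per day.  Reading validates the series: dates must parse,
#' be unique and gap-free, and counts must be non-negative; violations are
#' reported with the offending date or row.
#'
#' @param path file path.
#' @return `read_daily_counts` returns a `daily_counts` object;
#'   `write_daily_counts` returns `path` invisibly.
#' @export
read_daily_counts <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(raw)))
    stop("expected columns 'date' and 'count' in ", path)
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(d)) {
    i <- which(is.na(d))[1L]
    stop("malformed date at row ", i, ": '", raw$date[i], "'")
  }
  o <- order(d)
  daily_counts(d[o], raw$count[o])
}

#' @rdname read_daily_counts
#' @param x a `daily_counts` object.
#' @export
write_daily_counts <- function(x, path) {
  stopifnot(inherits(x, "daily_counts"))
  utils::write.csv(
    data.frame(date = format(x$date), count = x$count),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Trim a series to whole Monday-to-Sunday weeks
#'
#' Data from incomplete weekly cycles are excluded: the result starts on the
#' first Monday and ends on the last Sunday of the input, so its length is a
#' multiple of 7.
#'
#' @param x a `daily_counts` object.
#' @return a `daily_counts` object covering whole weeks.
#' @export
trim_to_whole_weeks <- function(x) {
  stopifnot(inherits(x, "daily_counts"))
  wd <- weekday_index(x)
  first <- match(1L, wd)
  last <- length(wd) + 1L - match(7L, rev(wd))
  if (is.na(first) || is.na(last) || last - first + 1L < 7L)
    stop("series contains no whole Monday-to-Sunday week")
  daily_counts(x$date[first:last], x$count[first:last])
}

#' Reshape a daily series into a week-by-weekday panel
#'
#' `to_panel` maps day `t` of a Monday-started, whole-week series to cell
#' (week `w`, weekday `tau`) with `t = 7 * (w - 1) + tau`; `from_panel`
#' inverts the reshape.  The panel is the natural view for the per-weekday
#' smoothing models and the singularity rules, which operate on one
#' weekday's values across weeks.
#'
#' @param x a `daily_counts` object starting on a Monday with length a
#'   multiple of 7.
#' @return `to_panel` returns a numeric matrix with one row per week and
#'   columns Mon..Sun (class `weekday_panel`, start date kept as an
#'   attribute); `from_panel` returns a `daily_counts` object.
#' @export
to_panel <- function(x) {
  stopifnot(inherits(x, "daily_counts"))
  if (weekday_index(x$date[1L]) != 1L)
    stop("series must start on a Monday; use trim_to_whole_weeks() first")
  n <- nrow(x)
  if (n %% 7L != 0L)
    stop("series length (", n, ") is not a multiple of 7; ",
         "use trim_to_whole_weeks() first")
  m <- matrix(x$count, ncol = 7L, byrow = TRUE,
              dimnames = list(NULL, WEEKDAYS))
  structure(m, start_date = x$date[1L], class = c("weekday_panel", class(m)))
}

#' @rdname to_panel
#' @param panel a `weekday_panel` matrix.
#' @param start_date Monday date of the first row; defaults to the date
#'   recorded when the panel was built.
#' @export
from_panel <- function(panel, start_date = attr(panel, "start_date")) {
  if (is.null(start_date)) stop("panel carries no start date; supply one")
  n <- length(panel)
  daily_counts(seq(as.Date(start_date), by = "day", length.out = n),
               as.numeric(t(unclass(panel))))
}

WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
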