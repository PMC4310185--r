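#' Discrete timeline for event series
#'
#' A timeline discretizes calendar time into `n_units` consecutive units of
#' fixed width, indexed 1, 2, ..., T, starting at `origin`. Units are either
#' days or 30-day months; the 30-day month keeps all bandwidth and delay
#' arithmetic deterministic and calendar-independent.
#'
#' @param origin Calendar date (`Date` or ISO-8601 string) of the first unit.
#' @param n_units Positive integer, the number of discrete time units T.
#' @param unit `"month"` (30 days) or `"day"`.
#' @return An object of class `ehr_timeline`.
#' @examples
#' tl <- timeline("2003-01-01", n_units = 108, unit = "month")
#' date_to_index(as.Date("2003-02-15"), tl)
#' @export
timeline <- function(origin, n_units, unit = c("month", "day")) {
  unit <- match.arg(unit)
  origin <- as.Date(origin)
  if (is.na(origin)) stop("`origin` must be a valid date", call. = FALSE)
  n_units <- as.integer(n_units)
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1L)
    stop("`n_units` must be a positive integer", call. = FALSE)
  structure(
    list(origin = origin, n_units = n_units, unit = unit),
    class = "ehr_timeline"
  )
}

#' @export
print.ehr_timeline <- function(x, ...) {
  cat(sprintf("<ehr_timeline> %d %ss from %s\n", x$n_units, x$unit,
              format(x$origin)))
  invisible(x)
}

# width of one unit in days; a month is fixed at 30 days
unit_days <- function(tl) if (tl$unit == "day") 1L else 30L

# number of units per month, used to convert month-valued bandwidths,
# delays, horizons and lookbacks into timeline units
units_per_month <- function(tl) if (tl$unit == "day") 30L else 1L

#' Map a calendar date to its 1-based timeline index
#'
#' @param d Vector of dates (`Date` or coercible).
#' @param tl An [timeline()] object.
#' @return Integer vector of 1-based unit indices. Dates past the end of the
#'   timeline return indices greater than `tl$n_units` (callers drop them);
#'   dates before the origin are an error.
#' @export
date_to_index <- function(d, tl) {
  stopifnot(inherits(tl, "ehr_timeline"))
  d <- as.Date(d)
  offs <- as.integer(d - tl$origin)
  if (any(offs < 0L, na.rm = TRUE))
    stop("date before timeline origin", call. = FALSE)
  offs %/% unit_days(tl) + 1L
}

#' First calendar date of a timeline unit
#'
#' @param t Integer vector of unit indices.
#' @param tl An [timeline()] object.
#' @return `Date` vector.
#' @export
index_to_date <- function(t, tl) {
  stopifnot(inherits(tl, "ehr_timeline"))
  tl$origin + (as.integer(t) - 1L) * unit_days(tl)
}
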