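# Calendar helpers shared across modules.  All public functions accept Date
# vectors (or strings coercible via as.Date).

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    stop(sprintf("invalid %s: %s", what, paste(utils::head(x, 3), collapse = ", ")),
         call. = FALSE)
  }
  out
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

date_year  <- function(d) as.integer(format(d, "%Y"))
date_month <- function(d) as.integer(format(d, "%m"))
date_mday  <- function(d) as.integer(format(d, "%d"))

# ISO day of week, 1 = Monday .. 7 = Sunday
date_dow <- function(d) as.integer(format(d, "%u"))

#' Day of year on a fixed 365-bin scale
#'
#' Maps a calendar date to a day-of-year index in 1..365.  February 29 shares
#' bin 59 with February 28, so the same (month, day) always lands in the same
#' bin regardless of leap years.  Used when collapsing multi-year daily series
#' by day of the year (e.g. for seasonal correlation heatmaps).
#'
#' @param dates Date vector (or coercible).
#' @return Integer vector in 1..365.
#' @examples
#' day_of_year_365(as.Date(c("2008-02-28", "2008-02-29", "2008-03-01")))
#' @export
day_of_year_365 <- function(dates) {
  dates <- as_date_strict(dates)
  offs <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
  m <- date_month(dates)
  day <- date_mday(dates)
  day[m == 2L & day == 29L] <- 28L
  offs[m] + day
}
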