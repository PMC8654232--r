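# Burden-based season definitions.  Seasons are defined by intra-annual
# periods of relative ED-visit burden rather than astronomical boundaries:
# winter Jan 1 - Feb 28/29, spring Mar 1 - May 31, summer Jun 1 - Aug 19,
# fall Aug 20 - Dec 31.  The four intervals partition the calendar year.

season_levels <- function() c("winter", "spring", "summer", "fall")

#' Season boundary table
#'
#' @return data.frame with season name and inclusive (month, day) start/end.
#' @export
season_definitions <- function() {
  data.frame(
    season = season_levels(),
    start_month = c(1L, 3L, 6L, 8L),
    start_day   = c(1L, 1L, 1L, 20L),
    end_month   = c(2L, 5L, 8L, 12L),
    end_day     = c(29L, 31L, 19L, 31L),  # Feb 29 included in winter
    stringsAsFactors = FALSE
  )
}

#' Assign burden-based seasons to dates
#'
#' Winter runs January 1 to the end of February (leap day included), spring
#' March 1 to May 31, summer June 1 to August 19, and fall August 20 (the
#' approximate start of the school year) to December 31.
#'
#' @param dates Date vector (or coercible).
#' @return factor with levels winter, spring, summer, fall.
#' @examples
#' assign_season(as.Date(c("2010-08-19", "2010-08-20", "2008-02-29")))
#' @export
assign_season <- function(dates) {
  dates <- as_date_strict(dates)
  key <- date_month(dates) * 100L + date_mday(dates)
  out <- character(length(key))
  out[key <= 229L] <- "winter"
  out[key >= 301L & key <= 531L] <- "spring"
  out[key >= 601L & key <= 819L] <- "summer"
  out[key >= 820L] <- "fall"
  factor(out, levels = season_levels())
}

#' Calendar days per season over a set of study years
#'
#' @param years integer vector of calendar years.
#' @return named integer vector (winter, spring, summer, fall) of total days;
#'   leap days count toward winter.
#' @export
season_day_counts <- function(years) {
  years <- as.integer(years)
  n_leap <- sum(is_leap_year(years))
  n <- length(years)
  c(winter = 59L * n + n_leap,  # Jan 31 + Feb 28 (+1 leap)
    spring = 92L * n,           # Mar 31 + Apr 30 + May 31
    summer = 80L * n,           # Jun 30 + Jul 31 + Aug 1-19
    fall   = 134L * n)          # Aug 20-31 + Sep 30 + Oct 31 + Nov 30 + Dec 31
}
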