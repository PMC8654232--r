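# Time-stratified design primitives: the year-month-day-of-week stratum index
# and matched referent-window selection.

#' Year-month-day-of-week stratum index
#'
#' Each combination of calendar year, month, and day of week defines one
#' stratum; over a 10-year study period there are 10 x 12 x 7 = 840 strata.
#' Case and referent windows of a visit always share a stratum because
#' referents are matched on exactly these three components.
#'
#' @param dates Date vector (or coercible).
#' @param study_years integer vector of consecutive study years (default
#'   2005:2014).  Dates outside these years are an error.
#' @return integer stratum index; a bijection from (year, month, weekday)
#'   combinations to `1 .. 84 * length(study_years)`.
#' @examples
#' stratum_index(as.Date("2010-02-09"))  # a Tuesday in Feb 2010
#' @export
stratum_index <- function(dates, study_years = 2005:2014) {
  dates <- as_date_strict(dates)
  study_years <- sort(as.integer(study_years))
  yr <- date_year(dates)
  if (any(yr < study_years[1] | yr > study_years[length(study_years)])) {
    stop("date outside the study year range", call. = FALSE)
  }
  (yr - study_years[1]) * 84L + (date_month(dates) - 1L) * 7L + date_dow(dates)
}

#' Select time-stratified referent dates for a case date
#'
#' Candidates are all dates in the same year and month as the case that share
#' its day of week, excluding the case date itself (a weekday occurs 4 or 5
#' times per month, so there are always 3 or 4 candidates).  When more than
#' three candidates exist, three are drawn uniformly without replacement;
#' otherwise all are returned.
#'
#' @param case_date a single Date (or coercible).
#' @param seed optional integer; when supplied the draw is made with a local,
#'   restored RNG state so repeated calls are reproducible and the caller's
#'   RNG is untouched.  When `NULL` the current RNG stream is used (callers
#'   such as [build_rows()] seed once and loop).
#' @return Date vector of up to three referent dates, sorted.
#' @examples
#' # the second Tuesday of February 2010 has exactly three other Tuesdays
#' select_referents(as.Date("2010-02-09"))
#' @export
select_referents <- function(case_date, seed = NULL) {
  case_date <- as_date_strict(case_date, "case date")
  if (length(case_date) != 1L) stop("`case_date` must be a single date", call. = FALSE)
  cand <- referent_candidates(case_date)
  if (length(cand) > 3L) {
    if (!is.null(seed)) {
      cand <- local_seed(seed, cand[sample.int(length(cand), 3L)])
    } else {
      cand <- cand[sample.int(length(cand), 3L)]
    }
  }
  sort(cand)
}

# All same year/month/day-of-week dates excluding the case date.
referent_candidates <- function(case_date) {
  first <- as.Date(sprintf("%04d-%02d-01", date_year(case_date), date_month(case_date)))
  month_days <- seq(first, by = "day", length.out = 31)
  month_days <- month_days[date_month(month_days) == date_month(case_date)]
  cand <- month_days[date_dow(month_days) == date_dow(case_date)]
  cand[cand != case_date]
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
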