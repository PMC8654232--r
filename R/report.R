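# Reporting surfaces: interquartile-range odds ratios with credible
# intervals, seasonal burden summaries, and descriptive stratification
# tables.

#' Interquartile range (linear-interpolation percentile rule)
#'
#' 75th minus 25th percentile with linear interpolation between order
#' statistics (R quantile type 7), computed over the case and referent
#' window values within the model's scope (overall or one season).
#'
#' @param values numeric vector, at least 4 values.
#' @return the IQR, native units.
#' @export
compute_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L) stop("need at least 4 values for an IQR", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] - q[1L]
}

#' Odds ratio per IQR increase with 95% credible interval
#'
#' Each posterior draw of a per-native-unit log-odds coefficient is scaled
#' to `exp(beta * iqr)`; the point estimate is the posterior median (or mean)
#' and the interval the 2.5th/97.5th percentiles of the scaled draws.
#'
#' @param beta_draws numeric vector of posterior coefficient draws (>= 100).
#' @param iqr positive interquartile range, native units.
#' @param point "median" (default) or "mean".
#' @return list with `or`, `lower`, `upper`, `iqr`, `significant` (interval
#'   excludes 1).
#' @export
or_iqr <- function(beta_draws, iqr, point = c("median", "mean")) {
  point <- match.arg(point)
  if (!is.numeric(iqr) || length(iqr) != 1L || !is.finite(iqr) || iqr <= 0) {
    stop("`iqr` must be a positive number", call. = FALSE)
  }
  if (length(beta_draws) < 100L) stop("need at least 100 draws", call. = FALSE)
  ors <- exp(beta_draws * iqr)
  est <- if (point == "median") median(ors) else mean(ors)
  ci <- quantile(ors, c(0.025, 0.975), names = FALSE, type = 7)
  list(or = est, lower = ci[1L], upper = ci[2L], iqr = iqr,
       significant = ci[1L] > 1 || ci[2L] < 1)
}

#' Odds-ratio table for a fitted model
#'
#' For each covariate, computes the IQR of its (case + referent) window
#' values in `rows` and scales the posterior coefficient draws to an odds
#' ratio per IQR increase.  IQRs are shift-invariant, so centred rows give
#' the same IQR as native-unit values.
#'
#' @param fit a `cco_fit`.
#' @param rows the `cco_rows` table the model was fitted to (its scope —
#'   overall or one season — determines the IQRs).
#' @param covariates covariates to report (default: the fitted covariates
#'   without the temperature-dewpoint interaction, whose IQR scaling is not
#'   meaningful).
#' @param point "median" or "mean" point estimate.
#' @return data.frame: covariate, or, lower, upper, iqr, significant.
#' @export
or_table <- function(fit, rows, covariates = setdiff(fit$covariates, "temp_dewp"),
                     point = c("median", "mean")) {
  point <- match.arg(point)
  m <- as_draws_matrix(fit)
  out <- do.call(rbind, lapply(covariates, function(v) {
    res <- or_iqr(m[, v], compute_iqr(rows[[v]]), point = point)
    data.frame(covariate = v, or = res$or, lower = res$lower,
               upper = res$upper, iqr = res$iqr,
               significant = res$significant, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Format an OR table in the three-line cell layout
#'
#' One block per covariate: OR estimate, 95% credible interval, IQR — ORs and
#' IQRs to three decimals.
#'
#' @param tab data.frame from [or_table()].
#' @return character vector of formatted lines.
#' @export
format_or_table <- function(tab) {
  unlist(lapply(seq_len(nrow(tab)), function(i) {
    c(sprintf("%-10s %.3f%s", tab$covariate[i], tab$or[i],
              if (tab$significant[i]) " *" else ""),
      sprintf("           (%.3f, %.3f)", tab$lower[i], tab$upper[i]),
      sprintf("           IQR %.3f", tab$iqr[i]))
  }))
}

#' Seasonal burden summary
#'
#' Visit counts, season day counts over the study years, and mean daily
#' visits (visits/day/year, one decimal) per burden-based season.
#'
#' @param visits data.frame with a `date` column, or `NULL` when
#'   `counts` is supplied directly.
#' @param study_years integer years of the study period (default: years of
#'   the visit dates).
#' @param counts optional named count vector (winter, spring, summer, fall)
#'   to use instead of tabulating `visits` — e.g. published table counts.
#' @return data.frame: season, n, days, mean_daily.
#' @export
burden_summary <- function(visits = NULL, study_years = NULL, counts = NULL) {
  if (is.null(counts)) {
    dates <- as_date_strict(visits$date, "visit date")
    if (is.null(study_years)) study_years <- sort(unique(date_year(dates)))
    tab <- table(assign_season(dates))
    counts <- as.integer(tab[season_levels()])
  } else {
    if (is.null(study_years)) stop("`study_years` required with `counts`", call. = FALSE)
    counts <- as.integer(counts[season_levels()])
  }
  days <- season_day_counts(study_years)
  data.frame(season = season_levels(), n = counts,
             days = as.integer(days[season_levels()]),
             mean_daily = round(counts / days[season_levels()], 1),
             stringsAsFactors = FALSE)
}

#' Descriptive stratification table with chi-square comparisons
#'
#' Counts and one-decimal percentages of visits per stratum for each
#' requested stratification, optionally compared against a reference
#' population distribution with a chi-square goodness-of-fit test.
#'
#' @param visits data.frame with one column per stratification.
#' @param stratifications columns to tabulate (default: the conventional
#'   demographic set present in `visits`, plus season when a `date` column
#'   exists).
#' @param reference optional named list: per stratification, a named count
#'   (or proportion) vector over the same stratum labels.
#' @return data.frame: stratification, stratum, n, pct, p_value (the test's
#'   p-value on the first row of its stratification; NA without a
#'   reference), warning annotation when an expected cell count is < 5 or
#'   the table is degenerate.
#' @export
stratified_table <- function(visits, stratifications = NULL, reference = NULL) {
  if (is.null(stratifications)) {
    stratifications <- intersect(c("sex", "age_group", "race", "payor",
                                   "region", "season"), names(visits))
    if ("date" %in% names(visits) && !"season" %in% names(visits)) {
      visits$season <- assign_season(visits$date)
      stratifications <- c(stratifications, "season")
    }
  } else if ("season" %in% stratifications && !"season" %in% names(visits)) {
    visits$season <- assign_season(visits$date)
  }
  out <- list()
  for (s in stratifications) {
    tab <- table(visits[[s]])
    tab <- tab[tab > 0 | names(tab) %in% names(reference[[s]])]
    n <- as.integer(tab)
    pct <- round(100 * n / sum(n), 1)
    p_value <- NA_real_
    note <- ""
    if (!is.null(reference[[s]])) {
      ref <- reference[[s]][names(tab)]
      if (anyNA(ref)) stop(sprintf("reference for '%s' lacks some strata", s),
                           call. = FALSE)
      expected <- sum(n) * ref / sum(ref)
      if (length(n) < 2L || any(n == sum(n))) {
        note <- "degenerate table"
      } else {
        test <- suppressWarnings(chisq.test(n, p = ref / sum(ref)))
        p_value <- test$p.value
        if (any(expected < 5)) note <- "expected cell count < 5"
      }
    } else if (length(n) < 2L || any(n == sum(n))) {
      note <- "degenerate table"
    }
    out[[s]] <- data.frame(stratification = s, stratum = names(tab), n = n,
                           pct = pct,
                           p_value = c(p_value, rep(NA_real_, length(n) - 1L)),
                           note = c(note, rep("", length(n) - 1L)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
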