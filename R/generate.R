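# Synthetic-data generators.  Exposure fields and visit events are produced
# with known parameters so every downstream stage (interpolation, referent
# selection, model fitting, OR_IQR reporting) can be validated by parameter
# recovery without any external data.

# AR(1) deviations with marginal sd `sd` and lag-1 autocorrelation `phi`,
# one independent series per tract (rows).
ar1_matrix <- function(n_tracts, n_days, phi, sd) {
  out <- matrix(0, n_tracts, n_days)
  if (sd <= 0 || n_days == 0L) return(out)
  innov_sd <- sd * sqrt(1 - phi^2)
  out[, 1L] <- rnorm(n_tracts, 0, sd)
  if (n_days > 1L) {
    eps <- matrix(rnorm(n_tracts * (n_days - 1L), 0, innov_sd), n_tracts)
    for (d in 2:n_days) out[, d] <- phi * out[, d - 1L] + eps[, d - 1L]
  }
  out
}

seasonal_term <- function(doy, amplitude, peak_doy) {
  amplitude * cos(2 * pi * (doy - peak_doy) / 365.25)
}

# mean + seasonal + spatial gradient + AR(1) noise
build_variable <- function(par, doy, xnorm) {
  n_tracts <- length(xnorm); n_days <- length(doy)
  base <- matrix(rep(par$mean + seasonal_term(doy, par$amplitude, par$peak_doy),
                     each = n_tracts), n_tracts) +
    par$gradient * (xnorm - 0.5)
  base + ar1_matrix(n_tracts, n_days, par$ar, par$sd)
}

#' Generate synthetic tract-level exposure and weather series
#'
#' Builds daily series for NOx, O3, SO2, PM2.5, PM10, the coarse fraction
#' PM10-2.5, CO, temperature and dewpoint at `n_tracts` synthetic tract
#' centroids.  Each series is a seasonal sinusoid plus a west-east spatial
#' gradient plus AR(1) day-to-day deviations; pollutants are truncated at 0.
#' PM10 is assembled as PM2.5 plus a nonnegative coarse component, so
#' PM10 >= PM2.5 holds by construction.  CO is driven by NOx (shared
#' combustion source) and dewpoint follows the temperature anomaly with
#' configurable correlation, inducing the cross-variable collinearity the
#' design-stage screen is meant to catch.  Fully reproducible under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return a [tract_series()] with variables nox, o3, so2, pm25, pm10,
#'   pm10_25, co, temp, dewp.
#' @export
generate_exposures <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  doy <- day_of_year_365(dates)
  nt <- config$n_tracts
  L <- config$domain_km

  centroids <- cbind(x = runif(nt, 0, L), y = runif(nt, 0, L))
  tract_ids <- sprintf("t%04d", seq_len(nt))
  xnorm <- centroids[, 1] / L

  vals <- list()
  for (v in names(config$pollutant_params)) {
    m <- build_variable(config$pollutant_params[[v]], doy, xnorm)
    m[m < 0] <- 0
    vals[[v]] <- m
  }
  # CO coupled to NOx
  if (!is.null(config$co_params) && !is.null(vals$nox)) {
    cop <- config$co_params
    co <- cop$intercept + cop$slope * vals$nox +
      ar1_matrix(nt, length(dates), cop$ar, cop$sd)
    co[co < 0] <- 0
    vals$co <- co
  }
  # PM10 from its parents; coarse component was generated nonnegative
  if (!is.null(vals$pm25) && !is.null(vals$pm10_25)) {
    vals$pm10 <- vals$pm25 + vals$pm10_25
  }

  # weather: temperature, then dewpoint tracking the temperature anomaly
  tp <- config$weather_params$temp
  temp_season <- seasonal_term(doy, tp$amplitude, tp$peak_doy)
  temp_dev <- ar1_matrix(nt, length(dates), tp$ar, tp$sd)
  vals$temp <- matrix(rep(tp$mean + temp_season, each = nt), nt) +
    tp$gradient * (xnorm - 0.5) + temp_dev
  dp <- config$weather_params$dewp
  dew_season <- 0.85 * temp_season
  own <- ar1_matrix(nt, length(dates), dp$ar, dp$sd * sqrt(max(0, 1 - dp$rho^2)))
  vals$dewp <- matrix(rep(dp$mean + dew_season, each = nt), nt) +
    dp$rho * (dp$sd / max(tp$sd, 1e-12)) * temp_dev + own

  order_vars <- c("nox", "o3", "so2", "pm25", "pm10", "pm10_25", "co",
                  "temp", "dewp")
  tract_series(tract_ids, centroids, dates, vals[intersect(order_vars, names(vals))])
}

baseline_logit_by_doy <- function(baseline, doy) {
  baseline$level +
    seasonal_term(doy, baseline$seasonal_amp, baseline$seasonal_peak_doy) +
    baseline$surge_height *
      exp(-0.5 * ((doy - baseline$surge_center) / baseline$surge_width)^2)
}

default_demo_probs <- function() {
  list(sex = c(male = 0.585, female = 0.415),
       age_group = c(`5-9` = 0.469, `10-14` = 0.288, `15-19` = 0.243),
       race = c(white = 0.267, african_american = 0.680, other = 0.053),
       payor = c(public = 0.583, private = 0.255, other = 0.162))
}

#' Generate synthetic ED-visit events from exposure series
#'
#' For every tract-day with a complete 3-day moving-average window, a visit
#' count is drawn from a Poisson distribution whose log intensity is the
#' seasonal day-of-year baseline (including the back-to-school surge) plus a
#' year-month-weekday stratum effect plus the inner product of `true_betas`
#' with the 3DMA covariates.  Counts are expanded to one record per visit
#' with pass-through demographic labels.  A Poisson event process on the
#' logit-scale linear predictor yields the same retrospective case-crossover
#' likelihood structure as a per-child Bernoulli model, which is
#' unidentifiable without a population register.
#'
#' @param exposures a [tract_series()] covering the config's date range.
#' @param config a [sim_config()]; `config$true_betas` holds the ground-truth
#'   per-native-unit log-odds.
#' @param seed RNG seed for the visit process (default `config$seed + 1`).
#' @param demo_probs named list of demographic label probabilities.
#' @return data.frame with columns visit_id, date, tract_id, sex, age_group,
#'   race, payor, region, plus attributes `expected_total` and `stratum_sd`.
#' @export
generate_visits <- function(exposures, config, seed = config$seed + 1L,
                            demo_probs = default_demo_probs()) {
  stopifnot(inherits(exposures, "tract_series"), inherits(config, "sim_config"))
  if (min(exposures$dates) > config$date_range[1] ||
      max(exposures$dates) < config$date_range[2]) {
    stop("exposures do not cover the configured date range", call. = FALSE)
  }
  set.seed(seed)
  dates <- exposures$dates
  keep <- dates >= config$date_range[1] & dates <= config$date_range[2]
  doy <- day_of_year_365(dates)
  nt <- length(exposures$tract_ids)
  nd <- length(dates)

  loglam <- matrix(rep(baseline_logit_by_doy(config$baseline, doy), each = nt), nt)

  years <- sort(unique(date_year(dates)))
  sidx <- stratum_index(dates, study_years = years)
  d_eff <- rnorm(84L * length(years), 0, config$stratum_sd)
  loglam <- loglam + matrix(rep(d_eff[sidx], each = nt), nt)

  betas <- config$true_betas
  if (!is.null(betas) && length(betas)) {
    for (v in names(betas)) {
      if (betas[[v]] == 0) next
      loglam <- loglam + betas[[v]] * tdma_matrix(series_matrix(exposures, v))
    }
  }

  lam <- exp(loglam)
  # no complete 3DMA window on the first two days; exclude them and any
  # missing-covariate cells
  lam[, 1:min(2L, nd)] <- 0
  lam[!keep[col(lam)]] <- 0
  lam[!is.finite(lam)] <- 0
  if (!is.null(config$target_total_visits)) {
    tot <- sum(lam)
    if (tot > 0) lam <- lam * (config$target_total_visits / tot)
  }
  if (sum(lam) == 0) {
    warning("expected visit total is 0; returning no visits")
    return(empty_visits())
  }

  counts <- matrix(rpois(length(lam), lam), nt)
  idx <- which(counts > 0, arr.ind = TRUE)
  n_rep <- counts[idx]
  tract_i <- rep(idx[, 1L], n_rep)
  day_i <- rep(idx[, 2L], n_rep)
  ord <- order(day_i, tract_i)
  tract_i <- tract_i[ord]; day_i <- day_i[ord]
  n <- length(tract_i)

  region <- cut(exposures$centroids[, 1],
                breaks = quantile(exposures$centroids[, 1], c(0, 1/3, 2/3, 1)),
                labels = c("upstate", "midlands", "lowcountry"),
                include.lowest = TRUE)
  draw <- function(p, n) sample(names(p), n, replace = TRUE, prob = p)
  visits <- data.frame(
    visit_id = sprintf("v%06d", seq_len(n)),
    date = dates[day_i],
    tract_id = exposures$tract_ids[tract_i],
    sex = draw(demo_probs$sex, n),
    age_group = draw(demo_probs$age_group, n),
    race = draw(demo_probs$race, n),
    payor = draw(demo_probs$payor, n),
    region = as.character(region[tract_i]),
    stringsAsFactors = FALSE
  )
  attr(visits, "expected_total") <- sum(lam)
  attr(visits, "stratum_sd") <- config$stratum_sd
  visits
}

empty_visits <- function() {
  data.frame(visit_id = character(), date = as.Date(character()),
             tract_id = character(), sex = character(),
             age_group = character(), race = character(),
             payor = character(), region = character(),
             stringsAsFactors = FALSE)
}

#' Write / read visit records as CSV
#'
#' @param visits visit data.frame as from [generate_visits()].
#' @param path CSV file path.
#' @export
write_visits <- function(visits, path) {
  write.csv(visits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  v <- read.csv(path, stringsAsFactors = FALSE)
  v$date <- as.Date(v$date)
  v
}
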