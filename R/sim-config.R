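# Simulation configuration for the synthetic-data module.
#
# Defaults emulate the study conditions of a low-air-pollution south-eastern
# US state: ~1,079 census tracts, a 10-year daily series (2005-2014), six
# criteria pollutants plus temperature and dewpoint with seasonal cycles and
# cross-pollutant correlation, and visit events whose log intensity follows
# the same logit-scale linear predictor the hierarchical model assumes.
# Units follow the reporting convention: NOx and SO2 in ppb, O3 and CO in
# ppm, PM in ug/m3, temperatures in deg C, so interquartile ranges land at
# realistic magnitudes.

#' Per-variable generator parameters
#'
#' Each daily tract-level series is built as
#' `mean + amplitude * cos(2*pi*(doy - peak_doy)/365.25) + gradient * (x/L - 1/2) + AR(1) deviation`,
#' where the AR(1) deviation has marginal standard deviation `sd` and
#' day-to-day (lag-1) autocorrelation `ar`.  Pollutants are truncated at 0.
#'
#' @param mean annual mean, native units.
#' @param amplitude seasonal amplitude (peak deviation from the mean).
#' @param peak_doy day of year at which the seasonal cycle peaks.
#' @param ar lag-1 autocorrelation of the deviation process, in `[0, 1)`.
#' @param sd marginal standard deviation of the deviation process (>= 0).
#' @param gradient west-to-east spatial gradient strength (native units per
#'   full domain width).
#' @return list of class `variable_params`.
#' @export
variable_params <- function(mean, amplitude = 0, peak_doy = 15,
                            ar = 0, sd = 0, gradient = 0) {
  if (ar < 0 || ar >= 1) stop("`ar` must be in [0, 1)", call. = FALSE)
  if (sd < 0) stop("`sd` must be nonnegative", call. = FALSE)
  structure(list(mean = mean, amplitude = amplitude, peak_doy = peak_doy,
                 ar = ar, sd = sd, gradient = gradient),
            class = "variable_params")
}

default_pollutant_params <- function() {
  list(
    nox  = variable_params(mean = 12,    amplitude = 5,     peak_doy = 15,
                           ar = 0.75, sd = 5,     gradient = 4),
    o3   = variable_params(mean = 0.040, amplitude = 0.011, peak_doy = 196,
                           ar = 0.70, sd = 0.007, gradient = 0.003),
    pm25 = variable_params(mean = 10.5,  amplitude = 2.8,   peak_doy = 200,
                           ar = 0.65, sd = 3.2,   gradient = 1.5),
    # coarse component; pm10 is assembled as pm25 + coarse so pm10 >= pm25
    pm10_25 = variable_params(mean = 4.5, amplitude = 1.2,  peak_doy = 170,
                           ar = 0.50, sd = 2.8,   gradient = 1.0),
    so2  = variable_params(mean = 3.8,   amplitude = 1.2,   peak_doy = 20,
                           ar = 0.60, sd = 2.6,   gradient = 1.2)
  )
}

default_weather_params <- function() {
  list(
    temp = variable_params(mean = 17.5, amplitude = 8.5, peak_doy = 200,
                           ar = 0.80, sd = 3.0, gradient = 1.5),
    # dewpoint follows the temperature anomaly with correlation `rho`
    dewp = list(mean = 11.5, rho = 0.9, sd = 2.5, ar = 0.75)
  )
}

# CO is driven by NOx (shared combustion source): co = intercept + slope*nox
# + small AR noise, which reproduces the high CO-NOx collinearity that leads
# to CO's removal in the screen.
default_co_params <- function() {
  list(intercept = 0.10, slope = 0.018, sd = 0.03, ar = 0.5)
}

default_baseline <- function() {
  # log daily visit intensity per tract by day of year: annual cycle plus a
  # smooth back-to-school surge centred on day 236 (Aug 24)
  list(level = -4.3, seasonal_amp = 0.25, seasonal_peak_doy = 300,
       surge_height = 0.9, surge_center = 236, surge_width = 12)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults emulate
#' the target study: 1,079 tracts, daily series 2005-01-01 to 2014-12-31, six
#' criteria pollutants plus temperature/dewpoint, and a visit process with a
#' seasonal baseline, a late-August back-to-school surge, year-month-weekday
#' stratum effects, and known per-unit log-odds coefficients (`true_betas`,
#' default all zero).
#'
#' @param n_tracts number of census tracts (>= 1).
#' @param date_range inclusive Date interval `c(start, end)`.
#' @param pollutant_params named list of [variable_params()] for nox, o3,
#'   pm25, pm10_25 (coarse component) and so2.
#' @param weather_params list with `temp` ([variable_params()]) and `dewp`
#'   (mean, rho, sd, ar), `rho` being the temperature-dewpoint anomaly
#'   correlation.
#' @param co_params CO coupling to NOx: intercept, slope, sd, ar.
#' @param true_betas named numeric vector of per-native-unit log-odds for any
#'   subset of the generated variables (by 3DMA); unnamed variables get 0.
#' @param baseline list: level, seasonal_amp, seasonal_peak_doy, surge_height,
#'   surge_center (day of year), surge_width (days).
#' @param stratum_sd standard deviation of the year-month-weekday stratum
#'   effects on the log intensity.
#' @param target_total_visits expected total visit count; the baseline level
#'   is rescaled so the expected total matches (NULL = use `level` as is).
#' @param domain_km side length of the square tract-centroid domain.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tracts = 1079,
                       date_range = as.Date(c("2005-01-01", "2014-12-31")),
                       pollutant_params = default_pollutant_params(),
                       weather_params = default_weather_params(),
                       co_params = default_co_params(),
                       true_betas = NULL,
                       baseline = default_baseline(),
                       stratum_sd = 0.1,
                       target_total_visits = 66092,
                       domain_km = 250,
                       seed = 1L) {
  if (n_tracts < 1) stop("`n_tracts` must be >= 1", call. = FALSE)
  date_range <- as_date_strict(date_range, "date range")
  if (length(date_range) != 2L || date_range[2] < date_range[1]) {
    stop("invalid date range: end before start", call. = FALSE)
  }
  for (p in pollutant_params) {
    if (p$ar < 0 || p$ar >= 1) stop("autocorrelation must be in [0, 1)", call. = FALSE)
    if (p$sd < 0) stop("noise sd must be nonnegative", call. = FALSE)
  }
  structure(list(n_tracts = as.integer(n_tracts), date_range = date_range,
                 pollutant_params = pollutant_params,
                 weather_params = weather_params, co_params = co_params,
                 true_betas = true_betas, baseline = baseline,
                 stratum_sd = stratum_sd,
                 target_total_visits = target_total_visits,
                 domain_km = domain_km, seed = as.integer(seed)),
            class = "sim_config")
}
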