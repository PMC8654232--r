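# Fixtures are built in code at test time; nothing is read from disk.

# A tiny deterministic two-tract series: linear-in-time values so expected
# 3DMAs are hand-computable.
tiny_series <- function(n_days = 40, start = "2010-01-01") {
  dates <- as.Date(start) + seq_len(n_days) - 1L
  t1 <- seq_len(n_days)                 # 1, 2, 3, ...
  vals <- list(
    nox  = rbind(t1, t1 + 10),          # tract 2 offset by 10
    temp = rbind(rep(5, n_days), rep(7, n_days))
  )
  vals <- lapply(vals, function(m) { dimnames(m) <- NULL; m })
  tract_series(c("A", "B"), cbind(c(0, 10), c(0, 0)), dates, vals)
}

# Visits placed on explicit dates/tracts.
visits_on <- function(dates, tracts = "A") {
  n <- length(dates)
  data.frame(visit_id = sprintf("v%03d", seq_len(n)),
             date = as.Date(dates),
             tract_id = rep_len(tracts, n),
             stringsAsFactors = FALSE)
}

# Simulation settings for the parameter-recovery experiments: a single
# causal pollutant whose 3DMA variance is dominated by day-to-day (within
# year-month stratum) variation, 30 tracts, ~2,000 visits over the full
# 10-year calendar.  beta_true is set so that an interquartile-range
# increase of the 3DMA (IQR ~ 5.3 ppb under these settings) multiplies the
# odds by 1.15.
recovery_beta_true <- function() log(1.15) / 5.3

recovery_config <- function(seed, beta = recovery_beta_true()) {
  sim_config(
    n_tracts = 30, target_total_visits = 2000, seed = seed,
    true_betas = c(nox = beta),
    pollutant_params = list(
      nox = variable_params(mean = 12, amplitude = 0.5, peak_doy = 15,
                            ar = 0.5, sd = 5, gradient = 1)))
}

# One full generate -> design -> fit pass under the recovery settings.
recovery_fit <- function(seed, beta = recovery_beta_true(),
                         n_iter = 1500, n_burnin = 500, n_chains = 1) {
  cfg <- recovery_config(seed, beta)
  ex <- generate_exposures(cfg)
  v <- generate_visits(ex, cfg)
  rows <- build_rows(v, ex, covariates = "nox", seed = seed)
  rows_c <- center_covariates(rows, "nox")
  fit <- fit_mcmc(rows_c, covariates = "nox", n_iter = n_iter,
                  n_burnin = n_burnin, n_chains = n_chains, seed = seed + 5000L)
  list(fit = fit, rows = rows_c)
}

# Small logistic dataset for reduced-model (no strata) checks.
reduced_data <- function(n = 300, alpha = -0.7, beta = 0.6, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(alpha + beta * x))
  data.frame(y = y, x = x)
}

# Minimal cco_fit skeleton for diagnostics tests.
fake_fit <- function(draws_list) {
  structure(list(draws = draws_list, n_chains = length(draws_list)),
            class = "cco_fit")
}
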