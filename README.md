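# aircco

Bayesian time-stratified case-crossover models for seasonal air-pollution
health effects.

`aircco` is an R package for epidemiologists studying short-term
associations between ambient air pollution, weather, and acute health
events such as pediatric asthma emergency-department (ED) visits — in
particular in mixed urban–rural settings with *low* pollution levels, where
effects are small and the visit burden follows "asthma seasons" (including a
late-August back-to-school surge) that do not line up with astronomical
seasons. It covers the full pipeline from gridded exposure fields to
odds-ratio tables, plus a synthetic-data module with known ground-truth
coefficients so every stage is testable by parameter recovery.

## The design and model

Each visit's exposure at the event time (the **case window**, a 3-day moving
average over lag days 0–2) is contrasted with the same individual's exposure
at up to three **referent windows** matched on year, month and day of week —
the time-stratified case-crossover design, which controls all time-invariant
confounding by construction. With visits *i* and windows *j* = 1…4:

    y_ij ~ Bernoulli(pi_ij)
    logit(pi_ij) = alpha + d_c + beta_p' X_ij + beta_w' W_ij

    beta_k | tau_k ~ N(0, 1/tau_k),    tau_k ~ Gamma(2, 1)        (shape, rate)
    alpha | sd_a   ~ N(0, sd_a^2),     sd_a  ~ Uniform(0, 4)
    d_c | tau_d    ~ N(0, 1/tau_d),    tau_d ~ Gamma(2, 0.5)

where `X` holds pollutant 3DMAs (NOx, O3, SO2, PM2.5, the coarse fraction
PM10-2.5), `W` temperature, dewpoint and their interaction, and `d_c` a
random effect for each of the 840 year × month × day-of-week strata of a
ten-year study period. Fitting is by adaptive Metropolis-within-Gibbs MCMC
(conjugate Gibbs steps for all precisions); effects are reported as odds
ratios per interquartile-range increase, `OR_IQR = exp(beta * IQR)`, with
95% equal-tailed credible intervals.

## Worked example

Simulate a null study (no true pollutant effects), build the case-crossover
table, screen collinear covariates, fit, and report (about two minutes):

```r
library(aircco)

cfg <- sim_config(n_tracts = 40, target_total_visits = 8000, seed = 7)
exposures <- generate_exposures(cfg)   # nox, o3, so2, pm25, pm10, pm10_25, co, temp, dewp
visits <- generate_visits(exposures, cfg)

burden_summary(visits)
#>        season    n days mean_daily
#> winter winter 1053  592        1.8
#> spring spring 1563  920        1.7
#> summer summer 1630  800        2.0
#> fall     fall 3799 1340        2.8

rows <- build_rows(visits, exposures, seed = 7)
screen <- collinearity_screen(rows)
screen$log
#>   step dropped against         r
#> 1    1    dewp    temp 0.9816265
#> 2    2      co     nox 0.9743613

rows_c <- center_covariates(rows)
fit <- fit_mcmc(rows_c, covariates = c(screen$retained, "temp_dewp"),
                n_iter = 4000, n_burnin = 2000, n_chains = 2, seed = 1)
or_table(fit, rows_c)
#>   covariate    or lower upper     iqr significant
#> 1       nox 1.021 0.976  1.07  8.1562       FALSE
#> 2        o3 1.001 0.976  1.02  0.0147       FALSE
#> 3       so2 1.008 0.969  1.05  3.0870       FALSE
#> 4      pm25 1.028 0.987  1.07  4.7314       FALSE
#> 5   pm10_25 1.025 0.986  1.06  3.1592       FALSE
#> 6      temp 0.985 0.920  1.05 11.3181       FALSE
```

The fall season carries the largest burden (2.8 visits/day/year here, driven
by the generator's back-to-school surge); the screen removes dewpoint
(collinear with temperature) and CO (collinear with NOx, their shared
combustion source); and, the data being null, every OR_IQR interval contains
1. Seasonal models subset rows by the case day's season
(`season_rows(rows, "fall")`), re-centre and refit. Convergence is checked
with `diagnostics(fit)` (split R-hat, effective sample size) and model
comparison with `dic(fit)`.

See `vignettes/aircco-methods.Rmd` for the full model description, prior
choices, sampler details, the synthetic-data generator's assumptions, and
the validation experiments.

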