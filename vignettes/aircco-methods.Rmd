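---
title: "Methods: Bayesian time-stratified case-crossover models in aircco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian time-stratified case-crossover models in aircco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Short-term ("acute") associations between ambient air pollution and asthma
emergency-department (ED) visits are usually studied in urban areas with
high pollution levels. aircco implements a pipeline for the harder setting:
a mixed urban–rural region with generally *low* pollutant levels, where
effects are small (odds ratios within a few percent of 1) and visit burden
is strongly seasonal — including a pronounced "back-to-school" surge in late
August — for reasons that are only partly environmental. The design of
choice is the **time-stratified case-crossover**: each child's exposure at
the time of their ED visit is contrasted with their own exposure at nearby
referent times, so every time-invariant personal and neighbourhood
characteristic is controlled by construction.

## Exposure preparation

Daily pollutant fields on a regular planar grid (as produced by
chemical-transport models at ~12 km resolution) are interpolated to
census-tract centroids by inverse distance weighting (`idw_interpolate()`).
The tract value is the weighted mean of the `k` nearest grid points with
finite values that day, with weights $d^{-p}$. The literature this design
follows names IDW but no parameters, so the defaults are the conventional
GIS choices $p = 2$, $k = 4$, both exposed as arguments; a centroid lying
exactly on a grid point receives that point's value, and a day on which all
usable neighbours are missing is flagged `NA` rather than imputed. Planar
coordinates are assumed: at a 12 km grid scale over a single state,
projection distortion is irrelevant to the quantities being tested.

Derived exposures:

* **Coarse particulate fraction** `pm10_25 = pm10 - pm25`
  (`coarse_fraction()`). Independent estimation error in the two parents can
  make the difference negative; because a mass fraction is physically
  nonnegative, negatives are clamped to 0 and counted in a diagnostic
  attribute rather than propagated.
* **3-day moving averages** (`moving_average_3day()`, `rolling_3dma()`) over
  lag days 0, 1, 2. A window missing any of its three days is unusable and
  flagged, and windows at the series start are dropped rather than
  shortened, keeping the window definition exact.
* **Season-stratified Spearman correlations** (`seasonal_spearman()`):
  series are averaged across tracts, collapsed by day of year (February 29
  shares bin 59 with February 28, keeping 365 bins), subset to a season, and
  rank-correlated. Collapsing across many tracts and years averages out
  day-to-day noise, so these correlations are dominated by the smooth
  seasonal components and sit close to ±1 for strongly seasonal variable
  pairs — useful for spotting shared cycles, not a test surface.

## Seasons and the time-stratified design

Seasons are defined by relative ED-visit burden rather than astronomically:
winter January 1 – February 28/29, spring March 1 – May 31, summer June 1 –
August 19, fall August 20 – December 31 (`assign_season()`); the fall
boundary approximates the start of the school year. The four intervals
partition the calendar exactly; over a 10-year study period they cover
3,652 days (leap days counted in winter).

Each visit's **case window** is the 3DMA centred on the admittance date.
**Referent windows** are 3DMAs centred on dates in the same year and month
sharing the case's day of week (`select_referents()`): a weekday occurs 4 or
5 times per month, so there are 3 or 4 candidates; when 4, three are drawn
uniformly without replacement under a caller-supplied seed. Year × month ×
day-of-week combinations define the stratum index (`stratum_index()`), 840
strata over ten years, shared by all windows of a visit. One sampling of
referents is reused across the overall and seasonal models, seed-controlled;
the season label of every row is taken from the case day, so referent
windows falling just across the August 19/20 boundary stay with their case's
season.

Covariates are mean-centred over the rows in the model's scope (all rows
for the overall model, one season's rows for a seasonal model;
`center_covariates()`). Whether centring should use case rows only is not
determinable from the source material; all rows are used, and the choice is
flagged for sensitivity. The temperature × dewpoint interaction is formed
from the centred main effects (which reduces its collinearity with them) and
then centred itself.

The **collinearity screen** (`collinearity_screen()`) iteratively removes
covariates until no retained pair has $|r| > 0.9$ (Pearson). The threshold
is a package choice — the source analysis reports which variables were
removed but no numeric rule. A fixed drop-priority list (CO before NOx,
dewpoint before temperature, SO2 before NOx) mirrors the conventional
removals; outside the list, the member of the offending pair with the larger
variance inflation factor is dropped. Under the default synthetic generator,
the screen reproduces the expected behaviour: CO (driven by NOx through
their shared combustion source) and dewpoint (tracking temperature) are
removed.

## The hierarchical model

With $i$ indexing visits and $j = 1, \dots, 4$ the case/referent windows,

$$y_{ij} \sim \text{Bernoulli}(\pi_{ij}), \qquad
\text{logit}(\pi_{ij}) = \alpha + d_c + \beta_p' X_{ij} + \beta_w' W_{ij}$$

with priors (Gamma in shape–rate convention, the BUGS reading of the
source's notation):

$$\beta_k \mid \tau_k \sim N(0, \tau_k^{-1}), \quad \tau_k \sim
\text{Gamma}(2, 1); \qquad
\alpha \mid \tau_\alpha \sim N(0, \tau_\alpha^{-1}), \quad \tau_\alpha =
sd_\alpha^{-2}, \quad sd_\alpha \sim U(0, 4);$$
$$d_c \mid \tau_d \sim N(0, \tau_d^{-1}), \quad \tau_d \sim
\text{Gamma}(2, 0.5).$$

Each coefficient gets its own precision $\tau_k$ (the "$\beta_*$" notation
is read per-coefficient); `shared_tau_beta = TRUE` switches to a single
shared precision. Only **occupied** strata receive a $d_c$ parameter —
an unoccupied stratum's effect would merely sample its prior.

This is the *unconditional* Bernoulli formulation with stratum random
effects, not classical conditional logistic regression; `survival::clogit`
on the same rows serves as an independent cross-check oracle in the test
suite, never as the implementation.

### Sampling

`fit_mcmc()` uses adaptive random-walk Metropolis for $\alpha$, each
$\beta_k$ and $sd_\alpha$, and a parallel single-site Metropolis update for
the whole $d_c$ block: given all other parameters, the full conditionals of
distinct strata are independent, so all stratum effects are proposed and
accepted/rejected simultaneously with per-stratum likelihood differences.
The precisions are conditionally conjugate and drawn by Gibbs:
$\tau_k \sim \text{Gamma}(2 + \tfrac12, 1 + \beta_k^2/2)$ and
$\tau_d \sim \text{Gamma}(2 + C/2, 0.5 + \sum_c d_c^2 / 2)$.

Step sizes adapt during burn-in by Robbins–Monro toward a 0.35 acceptance
rate. Defaults are 4 chains of 10,000 iterations with 5,000 burn-in, from
overdispersed starts, all configurable; the source analysis reports none of
these settings, so they are package choices. Likelihood evaluations use a
numerically stable log-sigmoid. Chains failing to find a finite starting
state redraw up to 20 times, then fail hard.

`diagnostics()` reports split R-hat (each chain halved) and a
Geyer-truncated autocorrelation ESS, flagging parameters with R-hat > 1.05.
`dic()` computes $\overline{D} + p_D$ with
$p_D = \overline{D} - D(\bar\theta)$, $\bar\theta$ the posterior mean of
intercept, coefficients and stratum effects.

### Reporting

Effects are reported as odds ratios per interquartile-range increase:
$\text{OR}_{IQR} = \exp(\beta \cdot IQR)$, applied per posterior draw, with
the posterior median as point estimate (a config switch selects the mean)
and an equal-tailed 95% interval from the 2.5th/97.5th percentiles — the
source calls its intervals credible intervals without specifying type, and
equal-tailed percentile intervals are the simplest reproducible reading.
IQRs use linear interpolation between order statistics (R quantile type 7),
computed over case *and* referent window values within the model's scope;
whether the original IQRs used case windows only is unknown, and this
choice is flagged for sensitivity. IQRs are shift-invariant, so centred and
native-unit rows give identical scaling.

## The synthetic-data generator

`generate_exposures()` builds each variable as
*annual mean + seasonal cosine + west–east gradient + AR(1) deviation*,
truncated at 0 for pollutants. Defaults emulate the study conditions:
1,079 tracts, daily series 2005–2014, units chosen so IQRs land at the
reported magnitudes (NOx ~12 ppb with 3DMA IQR near 14 ppb, O3 ~0.04 ppm,
PM2.5 ~10.5 µg/m³, temperature ~17.5 °C with amplitude 8.5 °C). The AR
parameter is the *lag-1 autocorrelation* and `sd` the *marginal* standard
deviation of the deviation process. Cross-variable correlation is induced
structurally rather than through a full covariance matrix: CO is an affine
function of NOx plus small noise (shared combustion source), dewpoint tracks
the temperature anomaly with correlation `rho`, and PM10 is PM2.5 plus a
nonnegative coarse component — so PM10 ≥ PM2.5 holds everywhere by
construction and the collinearity screen has realistic work to do. Noise is
independent across tracts (no spatially correlated weather systems), one of
the ways the generator is simpler than real data.

`generate_visits()` draws a Poisson count per tract-day whose log intensity
is a day-of-year baseline (annual cosine plus a Gaussian back-to-school bump
centred on day 236, i.e. August 24), a year-month-weekday stratum effect
(SD 0.1 by default), and the inner product of the ground-truth `true_betas`
with the 3DMA covariates. A per-child Bernoulli process is unidentifiable
without a population register; a thinned Poisson with the same linear
predictor yields the identical retrospective case-crossover likelihood,
because the design conditions on cases. The baseline level is rescaled so
the expected total matches `target_total_visits` (66,092 by default).
Demographic labels (sex, age group, race, payor) are pass-through draws at
the reported study frequencies; they exercise the descriptive tables only.

## Validation experiments and their problem sizes

The test suite validates every stage; the simulation experiments use these
sizes, chosen as the smallest at which the checks are statistically sharp:

* **Sampler correctness**: a reduced model (intercept + one covariate, no
  strata, n = 300) against a dense 4-dimensional grid-integration oracle —
  the likelihood depends only on $(\alpha, \beta)$, so the two
  hyperparameters integrate out as separable factors. Quantile agreement is
  required within Monte Carlo error (0.25 posterior SD at the median, 0.5 at
  the interval ends), at 3 seeds.
* **Parameter recovery**: 20 replicates of the full pipeline at 2,000
  visits over the 10-year calendar, one causal pollutant with
  $\beta = \log(1.15)/5.3$ per ppb so an IQR increase multiplies the odds
  by 1.15. The 95% interval must cover truth in ≥ 17 of 20 replicates and
  the median posterior median must sit within ±15% of $\beta$.
* **Null safety**: 20 replicates with all coefficients zero; the reported
  OR_IQR interval must contain 1 in ≥ 18.

A point worth making explicitly, because it shaped the recovery
experiment: the unconditional formulation identifies $\beta$ from
*within-stratum* exposure contrast. Case status is balanced within strata
by construction (each visit contributes one case and three referents to the
same stratum), so the $d_c$ are weakly identified at small n and the
hierarchy shrinks them strongly; exposure variance that lies *between*
strata — seasonal amplitude, fixed spatial offsets — then attenuates
$\hat\beta$. At the full study scale (~315 rows per stratum) this is
negligible, but at 2,000 visits it is visible when the tested exposure is
strongly seasonal. The recovery and null experiments therefore use an
exposure whose 3DMA variance is dominated by day-to-day variation
(autocorrelation 0.5, marginal SD 5 ppb, seasonal amplitude 0.5 ppb), the
regime in which the estimator is consistent for its target; a conditional
logistic fit on the same rows agrees within its standard error. Users
applying the model at small n to strongly seasonal exposures should expect
attenuation toward the null, not spurious signal.

What passing these tests does *not* show about real data: the generator has
no spatially correlated noise, no exposure measurement error relative to
personal exposure, no unmeasured time-varying confounders (pollen, viral
transmission), and demographic strata carry no differential effects. The
pipeline's inferential behaviour under those features is outside what
synthetic validation can establish.

## Degenerate inputs and numerical choices

* IDW with a centroid on a grid point returns the point value exactly
  (distance tolerance 1e-9); all-missing days propagate `NA`.
* Constant exposure series give IQR 0, which `or_iqr()` rejects — an OR per
  IQR increase is undefined without exposure variation.
* A single-row table centres to all zeros; centring twice is idempotent.
* The likelihood's log-sigmoid switches to its asymptote above $\eta = 35$,
  keeping `log_likelihood` finite and monotone into saturation.
* Ties in the collinearity screen resolve by the fixed priority list, then
  by larger VIF, making the screen deterministic.
* `compute_iqr` requires ≥ 4 values; `or_iqr` requires ≥ 100 draws.

## Worked example

```{r example}
library(aircco)

cfg <- sim_config(n_tracts = 40, target_total_visits = 8000, seed = 7)
exposures <- generate_exposures(cfg)
visits <- generate_visits(exposures, cfg)

burden_summary(visits)

rows <- build_rows(visits, exposures, seed = 7)
screen <- collinearity_screen(rows)
screen$log          # CO drops against NOx, dewpoint against temperature

rows_c <- center_covariates(rows)
fit <- fit_mcmc(rows_c, covariates = c(screen$retained, "temp_dewp"),
                n_iter = 4000, n_burnin = 2000, n_chains = 2, seed = 1)
diagnostics(fit)
or_table(fit, rows_c)

# seasonal model: subset rows by the case day's season, re-centre, refit
fall <- center_covariates(season_rows(rows, "fall"))
```
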