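# Independent oracles used by the tests.  These never call the code paths
# they check.

# Brute-force Bernoulli log-likelihood: per-row plogis + dbinom, no shared
# code with log_likelihood().
brute_force_loglik <- function(alpha, betas, d_by_stratum, rows, covariates) {
  total <- 0
  for (i in seq_len(nrow(rows))) {
    eta <- alpha
    for (k in seq_along(covariates)) {
      eta <- eta + betas[k] * rows[[covariates[k]]][i]
    }
    if (!is.null(d_by_stratum)) {
      eta <- eta + d_by_stratum[[as.character(rows$stratum[i])]]
    }
    p <- 1 / (1 + exp(-eta))
    total <- total + dbinom(rows$y[i], 1, p, log = TRUE)
  }
  total
}

# Brute-force referent enumeration: scan every day of the case month.
brute_force_referents <- function(case_date) {
  y <- as.integer(format(case_date, "%Y"))
  m <- as.integer(format(case_date, "%m"))
  all_days <- seq(as.Date(sprintf("%d-%02d-01", y, m)), by = "day",
                  length.out = 31)
  all_days <- all_days[as.integer(format(all_days, "%m")) == m]
  same_dow <- all_days[format(all_days, "%u") == format(case_date, "%u")]
  same_dow[same_dow != case_date]
}

# Sample lag-1 autocorrelation by the direct formula.
lag1_autocorr <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  sum(x[-1] * x[-n]) / sum(x^2)
}

# Dense grid-integration posterior for the reduced model
#   y ~ Bernoulli(plogis(alpha + beta x)),
#   alpha | sd_a ~ N(0, sd_a^2), sd_a ~ U(0, 4),
#   beta | tau ~ N(0, 1/tau),   tau ~ Gamma(2, 1).
# The likelihood depends only on (alpha, beta), so the two hyperparameters
# integrate out as separable factors on uniform grids.
grid_posterior <- function(y, x, na = 121, nb = 121, ns = 60, ntau = 120) {
  mle <- suppressWarnings(glm(y ~ x, family = binomial()))
  cf <- coef(mle); se <- sqrt(diag(vcov(mle)))
  agrid <- seq(cf[1] - 7 * se[1], cf[1] + 7 * se[1], length.out = na)
  bgrid <- seq(cf[2] - 7 * se[2], cf[2] + 7 * se[2], length.out = nb)
  sgrid <- seq(1e-3, 4 - 1e-3, length.out = ns)
  tgrid <- seq(1e-3, 15, length.out = ntau)

  ll <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    eta <- agrid[i] + bgrid[j] * x
    ll[i, j] <- sum(y * eta - log(1 + exp(eta)))
  }
  # SA_i = integral over sd_a of N(alpha_i | 0, sd_a^2) (uniform prior const)
  SA <- vapply(seq_len(na), function(i) {
    sum(dnorm(agrid[i], 0, sgrid))
  }, numeric(1))
  # SB_j = integral over tau of N(beta_j | 0, 1/tau) Gamma(tau | 2, 1)
  SB <- vapply(seq_len(nb), function(j) {
    sum(dnorm(bgrid[j], 0, 1 / sqrt(tgrid)) * dgamma(tgrid, 2, rate = 1))
  }, numeric(1))

  M <- max(ll)
  W <- exp(ll - M)              # na x nb
  pa <- rowSums(W * matrix(SB, na, nb, byrow = TRUE)) * SA
  pb <- colSums(W * SA) * SB
  list(alpha = list(grid = agrid, dens = pa / sum(pa)),
       beta = list(grid = bgrid, dens = pb / sum(pb)))
}

grid_quantile <- function(marg, probs) {
  cdf <- cumsum(marg$dens)
  stats::approx(cdf, marg$grid, xout = probs, rule = 2, ties = "ordered")$y
}

grid_sd <- function(marg) {
  mu <- sum(marg$grid * marg$dens)
  sqrt(sum((marg$grid - mu)^2 * marg$dens))
}
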