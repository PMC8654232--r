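# Model: likelihood, priors, sampler correctness, diagnostics, DIC.

toy_rows <- function() {
  data.frame(y = c(1L, 0L, 0L, 1L, 0L, 1L),
             x1 = c(0.5, -0.2, 1.1, 0.0, -1.3, 0.7),
             x2 = c(-1.0, 0.4, 0.2, 0.9, -0.5, 0.1),
             stratum = c(3L, 3L, 7L, 7L, 12L, 12L))
}

test_that("log-likelihood at the null state is N log(1/2)", {
  rows <- toy_rows()
  st <- list(alpha = 0, betas = c(0, 0), d = c(0, 0, 0))
  expect_equal(log_likelihood(st, rows, c("x1", "x2")), 6 * log(0.5))
})

test_that("log-likelihood matches the brute-force Bernoulli sum", {
  rows <- toy_rows()
  set.seed(2)
  for (rep in 1:5) {
    st <- list(alpha = rnorm(1), betas = rnorm(2),
               d = rnorm(3))
    got <- log_likelihood(st, rows, c("x1", "x2"))
    want <- brute_force_loglik(st$alpha, st$betas,
                               setNames(as.list(st$d), c("3", "7", "12")),
                               rows, c("x1", "x2"))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("log-likelihood saturates monotonically as alpha grows with y = 1", {
  rows <- data.frame(y = rep(1L, 4), x = rep(0, 4))
  lls <- vapply(c(1, 5, 10, 20, 35), function(a) {
    log_likelihood(list(alpha = a, betas = 0), rows, "x")
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
  expect_lt(abs(lls[5]), 1e-10)
  expect_true(all(lls <= 0))
  expect_true(all(lls[1:4] < 0))
})

test_that("log-prior matches closed forms and respects the support", {
  base <- list(alpha = 0.3, betas = c(0.1), sd_alpha = 1.5, tau_beta = 2,
               d = numeric(0), tau_d = NULL)
  out <- list(alpha = 0.3, betas = c(0.1), sd_alpha = 5, tau_beta = 2)
  expect_identical(log_prior(out), -Inf)
  expect_identical(log_prior(modifyList(base, list(tau_beta = -1))), -Inf)

  # Gamma(2, 0.5) log-density at tau = 1: log(0.25) - 0.5
  st1 <- list(alpha = 0, betas = numeric(0), sd_alpha = 1, tau_beta = numeric(0),
              d = c(0), tau_d = 1)
  st0 <- list(alpha = 0, betas = numeric(0), sd_alpha = 1, tau_beta = numeric(0),
              d = numeric(0), tau_d = NULL)
  delta <- log_prior(st1) - log_prior(st0)
  # one zero-valued d_c at tau_d = 1 contributes N(0,1) at 0, plus the tau_d prior
  expect_equal(delta, dnorm(0, log = TRUE) + log(0.25) - 0.5, tolerance = 1e-12)

  # doubling zero-valued d_c terms adds log(1/sqrt(2*pi)) each
  st2 <- modifyList(st1, list(d = c(0, 0)))
  expect_equal(log_prior(st2) - log_prior(st1), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("log-posterior decomposes exactly into likelihood plus prior", {
  rows <- toy_rows()
  set.seed(4)
  for (rep in 1:5) {
    st <- list(alpha = rnorm(1), betas = rnorm(2), d = rnorm(3),
               sd_alpha = runif(1, 0.1, 3.9), tau_beta = rgamma(2, 2, 1),
               tau_d = rgamma(1, 2, 0.5))
    expect_equal(log_posterior(st, rows, c("x1", "x2")),
                 log_likelihood(st, rows, c("x1", "x2")) + log_prior(st))
  }
})

test_that("likelihood is invariant to covariate shifts absorbed by alpha", {
  rows <- toy_rows()
  st <- list(alpha = 0.4, betas = c(0.8, -0.3), d = c(0.1, -0.2, 0.05))
  ll1 <- log_likelihood(st, rows, c("x1", "x2"))
  shift <- 2.5
  rows2 <- rows; rows2$x1 <- rows2$x1 + shift
  st2 <- st; st2$alpha <- st$alpha - st$betas[1] * shift
  expect_equal(log_likelihood(st2, rows2, c("x1", "x2")), ll1,
               tolerance = 1e-12)
})

test_that("the tau_d full conditional matches its conjugate Gamma moments", {
  set.seed(11)
  d <- rnorm(50, 0, 0.4)
  shape <- 2 + length(d) / 2
  rate <- 0.5 + sum(d^2) / 2
  draws <- aircco:::tau_gibbs_draw(d, 2, 0.5, n_draws = 40000)
  se_mean <- sqrt(shape) / rate / sqrt(40000)
  expect_lt(abs(mean(draws) - shape / rate), 4 * se_mean)
  expect_lt(abs(var(draws) - shape / rate^2) / (shape / rate^2), 0.1)
})

test_that("reduced-model posterior quantiles match dense grid integration", {
  dat <- reduced_data(n = 300, alpha = -0.7, beta = 0.6, seed = 5)
  oracle <- grid_posterior(dat$y, dat$x)
  for (sd_seed in c(101, 202, 303)) {
    fit <- fit_mcmc(dat, covariates = "x", n_iter = 4000, n_burnin = 1500,
                    n_chains = 2, seed = sd_seed, include_strata = FALSE)
    m <- as_draws_matrix(fit)
    for (par in c("alpha", "beta")) {
      col <- if (par == "alpha") "alpha" else "x"
      marg <- oracle[[par]]
      want <- grid_quantile(marg, c(0.025, 0.5, 0.975))
      got <- quantile(m[, col], c(0.025, 0.5, 0.975), names = FALSE)
      psd <- grid_sd(marg)
      expect_lt(abs(got[2] - want[2]), 0.25 * psd)  # median
      expect_lt(abs(got[1] - want[1]), 0.50 * psd)  # 2.5%
      expect_lt(abs(got[3] - want[3]), 0.50 * psd)  # 97.5%
    }
  }
})

test_that("a constant covariate returns its marginal prior (scaled t)", {
  set.seed(9)
  dat <- data.frame(y = rbinom(400, 1, 0.3), x = rep(0, 400))
  fit <- fit_mcmc(dat, covariates = "x", n_iter = 6000, n_burnin = 2000,
                  n_chains = 2, seed = 31, include_strata = FALSE)
  b <- as_draws_matrix(fit)[, "x"]
  # beta | tau ~ N(0, 1/tau), tau ~ Gamma(2, 1)  =>  beta ~ t_4 * sqrt(1/2)
  for (p in c(0.25, 0.75, 0.9)) {
    expect_lt(abs(quantile(b, p, names = FALSE) - qt(p, 4) * sqrt(0.5)), 0.08)
  }
})

test_that("posterior matches the conditional-logistic oracle on shared rows", {
  skip_if_not_installed("survival")
  skip_if_not_installed("withr")
  withr::local_package("survival")
  rf <- recovery_fit(seed = 400, n_iter = 1500, n_burnin = 500)
  med <- posterior_summary(rf$fit)["nox", "median"]
  cl <- survival::clogit(y ~ nox + survival::strata(visit_id), data = rf$rows)
  se <- sqrt(diag(vcov(cl)))[1]
  expect_lt(abs(med - coef(cl)[1]), 2 * se)
})

test_that("split R-hat and ESS behave on known chains", {
  set.seed(6)
  n <- 1500
  iid <- fake_fit(list(matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "p")),
                       matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "p"))))
  d <- diagnostics(iid)
  expect_gte(d$rhat, 1 - 1e-4)  # numerically at/above 1 for matched chains
  expect_lt(d$rhat, 1.02)
  expect_lt(abs(d$ess - 2 * n) / (2 * n), 0.2)
  expect_false(d$flagged)

  stuck <- fake_fit(list(matrix(0, n, 1, dimnames = list(NULL, "p")),
                         matrix(1, n, 1, dimnames = list(NULL, "p"))))
  d2 <- diagnostics(stuck)
  expect_true(d2$rhat > 1.05)
  expect_true(d2$flagged)

  one <- fake_fit(list(matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "p"))))
  expect_warning(d3 <- diagnostics(one), "single chain")
  expect_true(is.na(d3$rhat))
})

test_that("DIC matches a direct two-pass computation and degenerates to D", {
  dat <- reduced_data(n = 200, seed = 12)
  fit <- fit_mcmc(dat, covariates = "x", n_iter = 1200, n_burnin = 400,
                  n_chains = 2, seed = 55, include_strata = FALSE)
  got <- dic(fit)
  # independent two-pass oracle from the stored draws
  m <- as_draws_matrix(fit)
  ll_draw <- function(a, b) {
    eta <- a + b * dat$x
    sum(dat$y * eta - log(1 + exp(eta)))
  }
  dbar <- mean(-2 * vapply(seq_len(nrow(m)),
                           function(i) ll_draw(m[i, "alpha"], m[i, "x"]),
                           numeric(1)))
  dhat <- -2 * ll_draw(mean(m[, "alpha"]), mean(m[, "x"]))
  expect_equal(as.numeric(got), dbar + (dbar - dhat), tolerance = 1e-8)
  expect_equal(attr(got, "p_d"), dbar - dhat, tolerance = 1e-8)

  # all draws identical -> p_D = 0, DIC = deviance at that point
  deg <- fit
  deg$draws <- lapply(fit$draws, function(mm) {
    mm[] <- rep(colMeans(m), each = nrow(mm)); mm
  })
  deg$loglik <- lapply(fit$loglik, function(l) {
    rep(ll_draw(mean(m[, "alpha"]), mean(m[, "x"])), length(l))
  })
  dg <- dic(deg)
  expect_lt(abs(attr(dg, "p_d")), 1e-8)
  expect_equal(as.numeric(dg), attr(dg, "dhat"), tolerance = 1e-8)
})

test_that("adding a pure-noise covariate usually increases DIC", {
  worse <- 0L
  for (r in 1:20) {
    set.seed(700 + r)
    n <- 300
    x <- rnorm(n); z <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
    dat <- data.frame(y = y, x = x, z = z)
    f1 <- fit_mcmc(dat, covariates = "x", n_iter = 700, n_burnin = 300,
                   n_chains = 1, seed = r, include_strata = FALSE)
    f2 <- fit_mcmc(dat, covariates = c("x", "z"), n_iter = 700, n_burnin = 300,
                   n_chains = 1, seed = r, include_strata = FALSE)
    if (dic(f2) > dic(f1)) worse <- worse + 1L
  }
  expect_gt(worse, 10L)
})

test_that("fit rejects bad dimensions and iteration settings", {
  dat <- reduced_data(50)
  expect_error(fit_mcmc(dat, covariates = "nope", include_strata = FALSE),
               "missing covariate")
  expect_error(fit_mcmc(dat, covariates = "x", n_iter = 100, n_burnin = 100,
                        include_strata = FALSE), "exceed")
  rows <- toy_rows()
  expect_error(log_likelihood(list(alpha = 0, betas = 0), rows, c("x1", "x2")),
               "dimension")
})
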