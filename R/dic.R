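# Deviance information criterion for a fitted case-crossover model.

#' Deviance information criterion
#'
#' `DIC = Dbar + pD`, where `Dbar` is the posterior mean of the deviance
#' `D = -2 log L` over the retained draws and `pD = Dbar - D(theta_bar)` is
#' the effective number of parameters, with `theta_bar` the posterior mean of
#' the intercept, coefficients and stratum effects.
#'
#' @param fit a `cco_fit` from [fit_mcmc()] (stores per-draw log-likelihoods
#'   and the model design).
#' @return the DIC value, with attributes `p_d`, `dbar` and `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "cco_fit"))
  ll <- unlist(fit$loglik, use.names = FALSE)
  dbar <- mean(-2 * ll)
  m <- as_draws_matrix(fit)
  alpha_bar <- mean(m[, "alpha"])
  beta_bar <- colMeans(m[, fit$covariates, drop = FALSE])
  eta <- alpha_bar + as.vector(fit$design$X %*% beta_bar)
  if (fit$include_strata) eta <- eta + unname(fit$d_mean)[fit$design$strat]
  dhat <- -2 * sum(bernoulli_llvec(fit$design$y, eta))
  p_d <- dbar - dhat
  structure(dbar + p_d, p_d = p_d, dbar = dbar, dhat = dhat)
}
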