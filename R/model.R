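# Hierarchical Bernoulli-logit model for the case-crossover rows:
#
#   y_ij ~ Bernoulli(pi_ij)
#   logit(pi_ij) = alpha + d_c + beta' x_ij
#   beta_k | tau_k ~ Normal(0, 1/tau_k),   tau_k ~ Gamma(shape 2, rate 1)
#   alpha | tau_a ~ Normal(0, 1/tau_a),    tau_a = 1/sd_alpha^2,
#                                          sd_alpha ~ Uniform(0, 4)
#   d_c | tau_d ~ Normal(0, 1/tau_d),      tau_d ~ Gamma(shape 2, rate 0.5)
#
# Gamma distributions use the (shape, rate) convention throughout.  Sampling
# is adaptive random-walk Metropolis for alpha, each beta, sd_alpha and the
# stratum-effect block (whose full conditionals are mutually independent, so
# all d_c are proposed and accepted in parallel), with conjugate Gibbs draws
# for the precisions.

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  lo <- x <= 35
  out[lo] <- log1p(exp(x[lo]))
  out
}

bernoulli_llvec <- function(y, eta) y * eta - log1pexp(eta)

state_dims_check <- function(state, p, C) {
  if (length(state$betas) != p) stop("beta dimension mismatch", call. = FALSE)
  d <- if (is.null(state$d)) numeric(0) else state$d
  if (length(d) != C) stop("stratum-effect dimension mismatch", call. = FALSE)
  invisible(TRUE)
}

#' Model log-likelihood
#'
#' Sum over rows of the Bernoulli log-density with
#' `logit(pi) = alpha + d_c + beta' x`, computed with a numerically stable
#' log-sigmoid.
#'
#' @param state list with `alpha`, `betas` (one per covariate, in order) and,
#'   when the rows carry strata, `d` (one effect per occupied stratum, in
#'   increasing stratum order).
#' @param rows a centred `cco_rows` table (see [center_covariates()]).
#' @param covariates covariate columns matching `state$betas`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, rows, covariates = attr(rows, "covariates")) {
  X <- as.matrix(rows[, covariates, drop = FALSE])
  levels <- sort(unique(rows$stratum))
  C <- if (is.null(state$d)) 0L else length(levels)
  state_dims_check(state, ncol(X), C)
  eta <- state$alpha + as.vector(X %*% state$betas)
  if (C > 0L) eta <- eta + state$d[match(rows$stratum, levels)]
  sum(bernoulli_llvec(rows$y, eta))
}

#' Model log-prior
#'
#' Sum of the log prior densities: Normal(0, 1/tau_k) for each beta,
#' Gamma(2, 1) for each tau_k, Normal(0, sd_alpha^2) for alpha with
#' sd_alpha ~ Uniform(0, 4), and (when strata are present) Normal(0, 1/tau_d)
#' for each d_c with tau_d ~ Gamma(2, 0.5).  Returns `-Inf` outside the
#' support.
#'
#' @param state list with alpha, betas, sd_alpha, tau_beta (length 1, shared,
#'   or one per beta) and optionally d, tau_d.
#' @return scalar log prior density.
#' @export
log_prior <- function(state) {
  sd_alpha <- state$sd_alpha
  if (!is.finite(sd_alpha) || sd_alpha <= 0 || sd_alpha >= 4) return(-Inf)
  tau_b <- state$tau_beta
  if (any(!is.finite(tau_b)) || any(tau_b <= 0)) return(-Inf)
  p <- length(state$betas)
  tau_rep <- if (length(tau_b) == 1L) rep(tau_b, p) else tau_b
  if (length(tau_rep) != p) stop("tau_beta length mismatch", call. = FALSE)
  lp <- dunif(sd_alpha, 0, 4, log = TRUE) +
    dnorm(state$alpha, 0, sd_alpha, log = TRUE) +
    sum(dnorm(state$betas, 0, 1 / sqrt(tau_rep), log = TRUE)) +
    sum(dgamma(tau_b, shape = 2, rate = 1, log = TRUE))
  if (!is.null(state$d) && length(state$d)) {
    tau_d <- state$tau_d
    if (!is.finite(tau_d) || tau_d <= 0) return(-Inf)
    lp <- lp + sum(dnorm(state$d, 0, 1 / sqrt(tau_d), log = TRUE)) +
      dgamma(tau_d, shape = 2, rate = 0.5, log = TRUE)
  }
  lp
}

#' @rdname log_prior
#' @param rows,covariates as in [log_likelihood()].
#' @export
log_posterior <- function(state, rows, covariates = attr(rows, "covariates")) {
  lp <- log_prior(state)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(state, rows, covariates)
}

# Conjugate Gibbs draw for a Normal precision with Gamma(shape0, rate0)
# prior, given zero-mean values: Gamma(shape0 + n/2, rate0 + sum(v^2)/2).
tau_gibbs_draw <- function(values, shape0, rate0, n_draws = 1L) {
  rgamma(n_draws, shape = shape0 + length(values) / 2,
         rate = rate0 + sum(values^2) / 2)
}

#' Fit the hierarchical case-crossover model by MCMC
#'
#' Adaptive random-walk Metropolis updates for the intercept, each
#' coefficient, the stratum-effect block (proposed in parallel; the full
#' conditionals of distinct strata are independent) and `sd_alpha`, with
#' conjugate Gibbs draws for all precision parameters.  Step sizes adapt
#' during burn-in toward `target_accept`.  Chains start from overdispersed
#' draws and the whole run is reproducible under `seed`.
#'
#' @param rows a centred `cco_rows` table with columns `y`, `stratum` and the
#'   covariates.
#' @param covariates model covariates (default: the table's covariate set
#'   plus the `temp_dewp` interaction when present).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain.
#' @param n_chains number of chains.
#' @param thin thinning interval for retained draws.
#' @param seed integer RNG seed.
#' @param include_strata fit the year-month-weekday stratum random effects
#'   (TRUE, the full model) or omit them (reduced model).
#' @param shared_tau_beta use one shared precision for all betas instead of
#'   the default per-coefficient precisions.
#' @param target_accept Metropolis acceptance-rate target, default 0.35.
#' @param verbose print progress.
#' @return object of class `cco_fit`: per-chain draw matrices (`draws`),
#'   per-draw log-likelihoods (`loglik`), posterior-mean stratum effects
#'   (`d_mean`), acceptance rates, and the design (y, X, stratum index) used
#'   for [dic()].
#' @export
fit_mcmc <- function(rows, covariates = NULL, n_iter = 10000, n_burnin = 5000,
                     n_chains = 4, thin = 1, seed = 1L, include_strata = TRUE,
                     shared_tau_beta = FALSE, target_accept = 0.35,
                     verbose = FALSE) {
  if (is.null(covariates)) {
    covariates <- intersect(c(attr(rows, "covariates"), "temp_dewp"), names(rows))
  }
  if (!all(covariates %in% names(rows))) stop("missing covariate columns", call. = FALSE)
  if (n_iter <= n_burnin) stop("`n_iter` must exceed `n_burnin`", call. = FALSE)
  y <- rows$y
  X <- as.matrix(rows[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (include_strata) {
    levels <- sort(unique(rows$stratum))
    strat <- match(rows$stratum, levels)
    C <- length(levels)
  } else {
    levels <- integer(0); strat <- NULL; C <- 0L
  }
  p <- ncol(X)
  set.seed(seed)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (verbose) message(sprintf("chain %d/%d", ch, n_chains))
    chains[[ch]] <- run_chain(y, X, strat, C, n_iter, n_burnin, thin,
                              target_accept, shared_tau_beta)
  }
  d_mean <- if (C > 0L) {
    dm <- Reduce(`+`, lapply(chains, `[[`, "d_sum")) /
      sum(vapply(chains, `[[`, numeric(1), "n_kept"))
    names(dm) <- as.character(levels)
    dm
  } else NULL
  structure(list(
    draws = lapply(chains, `[[`, "draws"),
    loglik = lapply(chains, `[[`, "loglik"),
    accept = lapply(chains, `[[`, "accept"),
    d_mean = d_mean,
    covariates = covariates, stratum_levels = levels,
    n_iter = n_iter, n_burnin = n_burnin, n_chains = n_chains, thin = thin,
    seed = seed, include_strata = include_strata,
    shared_tau_beta = shared_tau_beta,
    design = list(y = y, X = X, strat = strat)
  ), class = "cco_fit")
}

run_chain <- function(y, X, strat, C, n_iter, n_burnin, thin, target_accept,
                      shared_tau) {
  N <- length(y); p <- ncol(X)
  sdx <- pmax(apply(X, 2L, sd), 1e-8)
  info <- N * 0.1875  # n * p(1-p) at the design's 1:3 case:referent ratio

  # overdispersed start; retry on non-finite posterior
  for (try in 1:20) {
    alpha <- rnorm(1, 0, 1)
    betas <- rnorm(p, 0, 0.5 / sdx)
    d <- if (C > 0L) rnorm(C, 0, 0.3) else numeric(0)
    sd_alpha <- runif(1, 0.5, 3.5)
    tau_beta <- rgamma(if (shared_tau) 1L else p, 2, 1)
    tau_d <- if (C > 0L) rgamma(1, 2, 0.5) else NULL
    eta <- alpha + as.vector(X %*% betas)
    if (C > 0L) eta <- eta + d[strat]
    llv <- bernoulli_llvec(y, eta)
    ll <- sum(llv)
    st <- list(alpha = alpha, betas = betas, d = if (C > 0L) d else NULL,
               sd_alpha = sd_alpha, tau_beta = tau_beta, tau_d = tau_d)
    if (is.finite(ll) && is.finite(log_prior(st))) break
    if (try == 20) stop("could not find a finite starting state", call. = FALSE)
  }

  ls_alpha <- log(2.5 / sqrt(info))
  ls_beta <- log(2.5 / (sdx * sqrt(info)))
  ls_sd <- log(0.3)
  if (C > 0L) {
    n_c <- tabulate(strat, C)
    ls_d <- log(2.5 / sqrt(pmax(n_c * 0.1875, 0.5)))
  }
  acc <- c(alpha = 0, sd_alpha = 0)
  acc_beta <- numeric(p); acc_d_total <- 0; n_post <- 0L

  n_kept <- (n_iter - n_burnin) %/% thin
  par_names <- c("alpha", colnames(X), "sd_alpha",
                 if (shared_tau) "tau_beta" else paste0("tau_", colnames(X)),
                 if (C > 0L) "tau_d")
  draws <- matrix(NA_real_, n_kept, length(par_names),
                  dimnames = list(NULL, par_names))
  loglik <- numeric(n_kept)
  d_sum <- numeric(C)
  kept <- 0L

  for (iter in seq_len(n_iter)) {
    adapting <- iter <= n_burnin
    gam <- if (adapting) min(0.25, 2 / sqrt(iter)) else 0

    # alpha
    prop <- alpha + rnorm(1, 0, exp(ls_alpha))
    eta_p <- eta + (prop - alpha)
    llv_p <- bernoulli_llvec(y, eta_p)
    logr <- sum(llv_p) - ll +
      dnorm(prop, 0, sd_alpha, log = TRUE) - dnorm(alpha, 0, sd_alpha, log = TRUE)
    a <- is.finite(logr) && log(runif(1)) < logr
    if (a) { alpha <- prop; eta <- eta_p; llv <- llv_p; ll <- sum(llv) }
    ls_alpha <- ls_alpha + gam * ((a) - target_accept)
    if (!adapting) acc["alpha"] <- acc["alpha"] + a

    # betas, one at a time
    tau_rep <- if (shared_tau) rep(tau_beta, p) else tau_beta
    for (j in seq_len(p)) {
      prop <- betas[j] + rnorm(1, 0, exp(ls_beta[j]))
      eta_p <- eta + X[, j] * (prop - betas[j])
      llv_p <- bernoulli_llvec(y, eta_p)
      logr <- sum(llv_p) - ll +
        dnorm(prop, 0, 1 / sqrt(tau_rep[j]), log = TRUE) -
        dnorm(betas[j], 0, 1 / sqrt(tau_rep[j]), log = TRUE)
      a <- is.finite(logr) && log(runif(1)) < logr
      if (a) { betas[j] <- prop; eta <- eta_p; llv <- llv_p; ll <- sum(llv) }
      ls_beta[j] <- ls_beta[j] + gam * ((a) - target_accept)
      if (!adapting) acc_beta[j] <- acc_beta[j] + a
    }

    # stratum effects: parallel single-site Metropolis (independent
    # conditionals given everything else)
    if (C > 0L) {
      prop_d <- d + rnorm(C, 0, exp(ls_d))
      eta_p <- eta + (prop_d - d)[strat]
      llv_p <- bernoulli_llvec(y, eta_p)
      rs <- rowsum(llv_p - llv, strat)
      delta <- numeric(C)
      delta[as.integer(rownames(rs))] <- rs[, 1L]
      sd_d_prior <- 1 / sqrt(tau_d)
      logr <- delta + dnorm(prop_d, 0, sd_d_prior, log = TRUE) -
        dnorm(d, 0, sd_d_prior, log = TRUE)
      a_c <- log(runif(C)) < logr
      a_c[!is.finite(logr)] <- FALSE
      if (any(a_c)) {
        upd <- a_c[strat]
        eta[upd] <- eta_p[upd]
        llv[upd] <- llv_p[upd]
        d[a_c] <- prop_d[a_c]
        ll <- sum(llv)
      }
      ls_d <- ls_d + gam * (a_c - target_accept)
      if (!adapting) acc_d_total <- acc_d_total + mean(a_c)
    }

    # sd_alpha on (0, 4): uniform prior cancels, only alpha's density moves
    prop <- sd_alpha + rnorm(1, 0, exp(ls_sd))
    if (prop > 0 && prop < 4) {
      logr <- dnorm(alpha, 0, prop, log = TRUE) -
        dnorm(alpha, 0, sd_alpha, log = TRUE)
      a <- log(runif(1)) < logr
      if (a) sd_alpha <- prop
    } else a <- FALSE
    ls_sd <- ls_sd + gam * ((a) - target_accept)
    if (!adapting) acc["sd_alpha"] <- acc["sd_alpha"] + a

    # conjugate Gibbs precisions
    tau_beta <- if (shared_tau) tau_gibbs_draw(betas, 2, 1)
                else vapply(betas, tau_gibbs_draw, numeric(1), shape0 = 2, rate0 = 1)
    if (C > 0L) tau_d <- tau_gibbs_draw(d, 2, 0.5)
    if (!adapting) n_post <- n_post + 1L

    if (iter > n_burnin && (iter - n_burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(alpha, betas, sd_alpha, tau_beta, if (C > 0L) tau_d)
      loglik[kept] <- ll
      if (C > 0L) d_sum <- d_sum + d
    }
  }

  accept <- c(alpha = unname(acc["alpha"]) / n_post,
              setNames(acc_beta / n_post, colnames(X)),
              sd_alpha = unname(acc["sd_alpha"]) / n_post,
              d_block = if (C > 0L) acc_d_total / n_post else NA_real_)
  list(draws = draws, loglik = loglik, accept = accept,
       d_sum = d_sum, n_kept = kept)
}

#' @export
print.cco_fit <- function(x, ...) {
  nk <- sum(vapply(x$draws, nrow, integer(1)))
  cat(sprintf("<cco_fit> %d chains x %d iterations (%d burn-in), %d retained draws\n",
              x$n_chains, x$n_iter, x$n_burnin, nk))
  cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  if (x$include_strata) {
    cat(sprintf("  stratum random effects: %d occupied strata\n",
                length(x$stratum_levels)))
  }
  q <- posterior_summary(x)
  print(round(q, 4))
  invisible(x)
}

#' Combine retained draws across chains
#'
#' @param fit a `cco_fit`.
#' @param params parameter names (default all).
#' @return matrix draws x parameters.
#' @export
as_draws_matrix <- function(fit, params = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(params)) m <- m[, params, drop = FALSE]
  m
}

#' Posterior medians and 95% equal-tailed intervals
#'
#' @param fit a `cco_fit`.
#' @return matrix with columns median, q2.5, q97.5.
#' @export
posterior_summary <- function(fit) {
  m <- as_draws_matrix(fit)
  t(apply(m, 2L, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)) |>
    `colnames<-`(c("median", "q2.5", "q97.5"))
}
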