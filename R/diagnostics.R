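# Convergence diagnostics: split R-hat and autocorrelation-based effective
# sample size, computed per parameter over the retained draws.

split_chains <- function(draws_list, param) {
  out <- list()
  for (m in draws_list) {
    v <- m[, param]
    n <- length(v)
    h <- n %/% 2L
    out <- c(out, list(v[seq_len(h)], v[(n - h + 1L):n]))
  }
  out
}

rhat_of <- function(seqs) {
  n <- min(lengths(seqs))
  seqs <- lapply(seqs, function(x) x[seq_len(n)])
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Geyer initial-positive-sequence truncated autocorrelation ESS, summed over
# chains.
ess_of <- function(chains) {
  total <- 0
  for (v in chains) {
    n <- length(v)
    if (var(v) == 0) next
    rho <- as.vector(acf(v, lag.max = min(n - 1L, 250L), plot = FALSE,
                         demean = TRUE)$acf)[-1L]
    s <- 0
    k <- 1L
    while (k + 1L <= length(rho)) {
      pair <- rho[k] + rho[k + 1L]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2L
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat (each chain halved, pooled-vs-within variance ratio) and an
#' autocorrelation-based effective sample size per parameter.  Parameters
#' with split R-hat above 1.05 are flagged.  With a single chain R-hat cannot
#' be computed and is omitted with a warning.
#'
#' @param fit a `cco_fit` from [fit_mcmc()].
#' @return data.frame with columns param, rhat, ess, flagged.
#' @export
diagnostics <- function(fit) {
  stopifnot(inherits(fit, "cco_fit"))
  params <- colnames(fit$draws[[1L]])
  single <- length(fit$draws) < 2L
  if (single) warning("single chain: R-hat omitted")
  out <- data.frame(param = params, rhat = NA_real_, ess = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(params)) {
    p <- params[i]
    if (!single) out$rhat[i] <- rhat_of(split_chains(fit$draws, p))
    out$ess[i] <- ess_of(lapply(fit$draws, function(m) m[, p]))
  }
  out$flagged <- !is.na(out$rhat) & out$rhat > 1.05
  out
}
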