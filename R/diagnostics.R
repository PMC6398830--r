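#' Gelman-Rubin potential scale reduction
#'
#' The classic between/within-chain variance ratio: with m chains of length n,
#' W is the mean within-chain variance, B/n the between-chain variance of the
#' chain means, and the statistic is sqrt(((n - 1)/n W + B/n) / W). Values
#' near 1 indicate the chains are sampling the same distribution.
#'
#' @param draws Either a matrix with one chain per row (chains x n), or a
#'   [coda::mcmc.list] of univariate chains.
#' @return Scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    draws <- do.call(rbind, lapply(draws, function(ch) as.numeric(ch)))
  }
  draws <- as.matrix(draws)
  m <- nrow(draws); n <- ncol(draws)
  if (m < 2L) abort("need at least 2 chains")
  means <- rowMeans(draws)
  W <- mean(apply(draws, 1, var))
  B_over_n <- var(means)
  vhat <- (n - 1) / n * W + B_over_n
  sqrt(vhat / W)
}

#' Batch-means Monte Carlo standard error
#'
#' Splits the chain into ceiling(sqrt(n)) consecutive batches and estimates
#' the Monte Carlo standard error of the posterior mean from the variance of
#' the batch means. Robust to the autocorrelation typical of MCMC output.
#'
#' @param x Numeric vector of draws (chains concatenated).
#' @return Scalar Monte Carlo standard error.
#' @export
mc_error <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) abort("too few draws")
  nb <- ceiling(sqrt(n))
  bs <- floor(n / nb)
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  sd(bm) / sqrt(nb)
}

#' Monte Carlo error acceptability check
#'
#' A parameter's chain passes when the batch-means Monte Carlo standard error
#' is below `threshold` times the posterior standard deviation — the usual
#' "MC error below 5% of the posterior sd" convergence rule.
#'
#' @param x Numeric vector of draws.
#' @param threshold Fraction of the posterior sd (default 0.05).
#' @return Logical.
#' @export
mc_error_ok <- function(x, threshold = 0.05) {
  if (length(x) < 50L) abort("need at least 50 draws")
  s <- sd(x)
  if (s == 0) return(TRUE)  # degenerate chain: the mean is exact
  mc_error(x) < threshold * s
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with pD = Dbar - D(posterior mean), where the deviance is
#' -2 times the Poisson outcome log likelihood. The plug-in deviance uses the
#' posterior mean of the log relative risk (rate parameterization). Smaller is
#' better; used to compare spline-knot configurations.
#'
#' @param fit A fitted model object from [fit_h2mjoint()], [fit_h2m()] or
#'   [fit_me()] run with `monitor_loglam = TRUE`.
#' @return A list with elements `dic`, `dbar`, `dhat` and `pd`.
#' @export
dic <- function(fit) {
  ll <- fit$loglam
  if (is.null(ll)) abort("fit was run without 'monitor_loglam = TRUE'")
  counts <- fit$outcome$counts
  E <- fit$outcome$E
  idx <- fit$outcome$kept_days
  O <- counts[idx]
  dev_draw <- apply(ll, 1, function(lp) -2 * sum(dpois(O, E * exp(lp), log = TRUE)))
  if (any(!is.finite(dev_draw))) abort("non-finite deviance")
  dbar <- mean(dev_draw)
  lphat <- colMeans(ll)
  dhat <- -2 * sum(dpois(O, E * exp(lphat), log = TRUE))
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd)
}

# Internal: per-parameter diagnostics table for a coda::mcmc.list.
diagnostics_table <- function(samples, mc_threshold = 0.05) {
  pars <- colnames(samples[[1]])
  nchains <- length(samples)
  rows <- lapply(pars, function(p) {
    chains <- do.call(rbind, lapply(samples, function(ch) as.numeric(ch[, p])))
    all_draws <- as.numeric(t(chains))
    tibble::tibble(
      term = p,
      rhat = if (nchains >= 2) gelman_rubin(chains) else NA_real_,
      mc_se = mc_error(all_draws),
      mc_ok = if (sd(all_draws) > 0) mc_error(all_draws) < mc_threshold * sd(all_draws) else TRUE
    )
  })
  dplyr::bind_rows(rows)
}
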