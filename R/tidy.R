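#' Tidy posterior summaries of a fitted model
#'
#' One row per monitored scalar parameter: posterior mean, posterior sd and
#' an equal-tailed credible interval.
#'
#' @param x An `h2m_fit`.
#' @param pars `"beta"` (pollutant health coefficients, per original
#'   concentration unit), `"sigma_proc"` (process sds, standardized scale),
#'   or `"all"` (every monitored scalar).
#' @param conf.level Credible level (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy h2m_fit
#' @export
tidy.h2m_fit <- function(x, pars = c("beta", "sigma_proc", "all"),
                         conf.level = 0.95, ...) {
  pars <- match.arg(pars)
  pooled <- pool_chains(x$samples)
  cols <- switch(pars,
                 beta = grep("^beta_", colnames(pooled), value = TRUE),
                 sigma_proc = grep("^sigma_proc_", colnames(pooled), value = TRUE),
                 all = colnames(pooled))
  a <- (1 - conf.level) / 2
  rows <- lapply(cols, function(cn) {
    d <- pooled[, cn]
    q <- quantile(d, c(a, 1 - a), names = FALSE)
    tibble::tibble(term = cn, estimate = mean(d), std.error = sd(d),
                   conf.low = q[1], conf.high = q[2])
  })
  dplyr::bind_rows(rows)
}

#' One-line model summary
#'
#' @param x An `h2m_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model label, dimensions, chain settings, worst
#'   Gelman-Rubin statistic, fraction of parameters passing the 5% MC-error
#'   rule, number of imputed measurement cells, and runtime.
#' @method glance h2m_fit
#' @export
glance.h2m_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_pollutants = length(x$pollutants),
    n_days = length(x$outcome$counts),
    n_chains = length(x$samples),
    n_keep = nrow(x$samples[[1]]),
    max_rhat = if (all(is.na(x$diagnostics$rhat))) NA_real_
               else max(x$diagnostics$rhat, na.rm = TRUE),
    mc_ok_frac = mean(x$diagnostics$mc_ok),
    n_imputed = x$options$n_missing %||% NA_integer_,
    runtime = x$runtime
  )
}
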