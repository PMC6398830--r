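#' Health-model linear predictor
#'
#' Builds the log relative risk of the Poisson health model:
#'
#' log lambda\[t\] = beta0 + sum_p beta\[p\] mu_orig\[t - health_lag, p\] +
#'   sum_i s(X\[t, i\]) + delta * holiday\[t\] + eps\[t\]
#'
#' Exposure enters at lag `health_lag` (default 1 day, the conventional choice
#' for short-term cardiovascular effects); the first `health_lag` days have no
#' lagged exposure and are returned as `NA`, to be excluded from the outcome
#' likelihood rather than padded.
#'
#' @param covariates A data frame with T rows; needs `temperature`,
#'   `rel_humidity`, `time_index` for any smoothed confounder in
#'   `state$splines`, and `holiday` if `state$delta` is nonzero.
#' @param mu_orig T x P matrix of concentrations on their original scales.
#' @param state A list with elements `beta0` (scalar), `beta` (length P),
#'   `splines` (possibly empty list of [spline_spec()]s named among
#'   `"time"`, `"temperature"`, `"rel_humidity"`), `delta` (scalar),
#'   `eps` (length T or scalar 0), and `health_lag` (non-negative integer).
#' @return Length-T vector; entries 1..health_lag are `NA`.
#' @export
health_linpred <- function(covariates, mu_orig, state) {
  mu_orig <- as.matrix(mu_orig)
  T_ <- nrow(mu_orig)
  if (nrow(covariates) != T_) abort("'covariates' and 'mu_orig' lengths differ")
  if (length(state$beta) != ncol(mu_orig)) abort("'beta' length must match pollutant count")
  hl <- state$health_lag %||% 1L
  if (hl < 0) abort("'health_lag' must be non-negative")
  lp <- rep(state$beta0, T_)
  if (hl > 0) {
    lagged <- rbind(matrix(NA_real_, hl, ncol(mu_orig)),
                    mu_orig[1:(T_ - hl), , drop = FALSE])
  } else {
    lagged <- mu_orig
  }
  lp <- lp + drop(lagged %*% state$beta)
  cov_x <- list(time = covariates$time_index,
                temperature = covariates$temperature,
                rel_humidity = covariates$rel_humidity)
  for (sp in state$splines %||% list()) {
    x <- cov_x[[sp$name]]
    if (is.null(x)) abort(paste0("no covariate for spline '", sp$name, "'"))
    lp <- lp + spline_eval(sp, x)
  }
  delta <- state$delta %||% 0
  if (delta != 0) lp <- lp + delta * as.numeric(covariates$holiday)
  eps <- state$eps %||% 0
  lp + eps
}

#' Poisson outcome log likelihood
#'
#' Sum over days t > `start` of the Poisson log density of the observed count
#' with rate E * exp(linpred\[t\]). `start` excludes the leading days without
#' lagged exposure.
#'
#' @param counts Length-T vector of non-negative integer counts.
#' @param linpred Length-T linear predictor (log relative risk).
#' @param E Positive expected daily count.
#' @param start Number of leading days to exclude (default 0).
#' @return Scalar log likelihood.
#' @export
outcome_loglik <- function(counts, linpred, E, start = 0L) {
  if (E <= 0) abort("'E' must be positive")
  if (any(counts < 0, na.rm = TRUE)) abort("negative counts")
  idx <- seq.int(start + 1L, length(counts))
  sum(dpois(counts[idx], E * exp(linpred[idx]), log = TRUE))
}

#' Percent increase per interquartile-range change
#'
#' Converts a log relative-rate coefficient per concentration unit into the
#' percent increase in the event rate for an IQR change in concentration:
#' (exp(beta * iqr) - 1) * 100. Applied per posterior draw and then
#' summarized, so that uncertainty propagates into the reported interval.
#'
#' @param beta Log relative rate per unit concentration (vectorized).
#' @param iqr Positive interquartile range, in the same concentration units.
#' @return Percent increase (same length as `beta`).
#' @export
percent_increase <- function(beta, iqr) {
  if (any(iqr <= 0)) abort("'iqr' must be positive")
  (exp(beta * iqr) - 1) * 100
}
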