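#' Covariate-driven latent pollutant mean
#'
#' The latent standardized concentration of pollutant p on day t is modelled
#' as a pollutant-specific intercept, linear and quadratic effects of daily
#' temperature and relative humidity, plus a residual temporal effect:
#'
#' mu\[t, p\] = gamma0\[p\] + gamma1\[p\] temp\[t\] + gamma2\[p\] temp\[t\]^2 +
#'   gamma3\[p\] rhum\[t\] + gamma4\[p\] rhum\[t\]^2 + theta\[t, p\]
#'
#' Covariates enter on their measured scale (degrees Celsius, percent).
#'
#' @param covariates A data frame with columns `temperature` and
#'   `rel_humidity` (T rows).
#' @param gamma P x 5 matrix of coefficients: intercept, temperature,
#'   temperature squared, humidity, humidity squared.
#' @param theta T x P matrix of residual temporal effects.
#' @return T x P matrix of latent means.
#' @export
pollutant_mean <- function(covariates, gamma, theta) {
  gamma <- as.matrix(gamma)
  theta <- as.matrix(theta)
  if (ncol(gamma) != 5L) abort("'gamma' must have 5 columns")
  if (nrow(theta) != nrow(covariates)) abort("'theta' and 'covariates' lengths differ")
  if (ncol(theta) != nrow(gamma)) abort("'theta' columns must match 'gamma' rows")
  X <- cbind(1, covariates$temperature, covariates$temperature^2,
             covariates$rel_humidity, covariates$rel_humidity^2)
  X %*% t(gamma) + theta
}

#' Measurement-layer log likelihood
#'
#' Sum over *observed* cells of the log Normal density of the measured
#' concentration Y\[t, p\] around the latent mean mu\[t, p\] with
#' pollutant-specific process standard deviation. Missing cells (NA in `Y`)
#' contribute zero, consistent with missingness completely at random.
#'
#' @param Y T x P matrix of measured concentrations, `NA` for missing.
#' @param mu T x P matrix of latent means.
#' @param sigma_proc Length-P vector of positive process standard deviations.
#' @return Scalar log likelihood.
#' @export
measurement_loglik <- function(Y, mu, sigma_proc) {
  Y <- as.matrix(Y); mu <- as.matrix(mu)
  if (!all(dim(Y) == dim(mu))) abort("'Y' and 'mu' dimensions differ")
  if (length(sigma_proc) != ncol(Y)) abort("'sigma_proc' must have one entry per pollutant")
  if (any(sigma_proc <= 0)) abort("'sigma_proc' must be positive")
  sdm <- matrix(sigma_proc, nrow(Y), ncol(Y), byrow = TRUE)
  ll <- dnorm(Y, mu, sdm, log = TRUE)
  sum(ll[!is.na(Y)])
}

#' Autoregressive residual-process log likelihood
#'
#' The residual temporal effects theta\[t, \] follow a driftless multivariate
#' random walk at lag `lag`: theta\[t, \] ~ MVN(theta\[t - lag, \], Sigma_P).
#' Rows t = lag+1, ..., T contribute the transition density; the first `lag`
#' rows receive a diffuse independent Normal(0, `init_sd`^2) initialization
#' prior per pollutant, which keeps the joint density proper.
#'
#' @param theta T x P matrix of residual effects.
#' @param Sigma_P P x P symmetric positive-definite innovation covariance.
#' @param lag Positive integer temporal lag (default 1).
#' @param init_sd Standard deviation of the initialization prior (default 10).
#' @return Scalar log likelihood (transition terms plus initialization prior).
#' @export
ar_residual_loglik <- function(theta, Sigma_P, lag = 1L, init_sd = 10) {
  theta <- as.matrix(theta)
  T_ <- nrow(theta); P <- ncol(theta)
  if (T_ <= lag) abort("need more rows than 'lag'")
  ch <- tryCatch(chol(Sigma_P), error = function(e) {
    abort("'Sigma_P' is not symmetric positive-definite")
  })
  logdet <- 2 * sum(log(diag(ch)))
  diffs <- theta[(lag + 1L):T_, , drop = FALSE] - theta[1:(T_ - lag), , drop = FALSE]
  # quadratic forms via the Cholesky factor: z = L^-T d  =>  d' Sigma^-1 d = z'z
  z <- backsolve(ch, t(diffs), transpose = TRUE)
  qf <- colSums(z^2)
  trans <- sum(-0.5 * (P * log(2 * pi) + logdet + qf))
  init <- sum(dnorm(theta[1:lag, , drop = FALSE], 0, init_sd, log = TRUE))
  trans + init
}

#' Back-transform latent concentrations to original units
#'
#' Health effects are interpreted per original concentration unit, so the
#' latent standardized concentrations are mapped back with the center/scale
#' recorded at standardization time: mu_orig = mu_std * scale + center.
#'
#' @param mu_std T x P matrix of standardized latent concentrations, columns
#'   ordered as in `scaling`.
#' @param scaling Either a tibble with columns `pollutant`, `center`, `scale`
#'   (as returned by [pollutant_scaling()]) or a data frame carrying a
#'   `"scaling"` attribute.
#' @return T x P matrix on the original scales.
#' @export
backtransform_mu <- function(mu_std, scaling) {
  if (is.data.frame(scaling) && !is.null(attr(scaling, "scaling"))) {
    scaling <- attr(scaling, "scaling")
  }
  if (!all(c("center", "scale") %in% names(scaling))) {
    abort("missing standardization parameters")
  }
  mu_std <- as.matrix(mu_std)
  if (ncol(mu_std) != nrow(scaling)) abort("'mu_std' columns must match scaling rows")
  sweep(sweep(mu_std, 2, scaling$scale, `*`), 2, scaling$center, `+`)
}
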