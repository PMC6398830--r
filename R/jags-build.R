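# Internal JAGS model-code assembly.
#
# The three estimators share building blocks:
#   * pollutant component: Normal measurement layer over latent standardized
#     concentrations whose residual temporal effects follow a driftless
#     multivariate random walk with inverse-Wishart innovation covariance;
#   * health component: Poisson counts with log-linear effects of (lagged)
#     concentrations on their original scale, optional penalized thin-plate
#     spline confounders, holiday term and overdispersion random effect.
# fit_h2mjoint() uses both blocks in one graph (feedback allowed);
# fit_h2m() runs the pollutant block alone, then cuts feedback (see
# cut-sampler.R); fit_me() uses the health block with measured
# concentrations plugged in as data. Switches include_Y / include_O drop the
# corresponding likelihood contributions for cut and prior-audit runs.

variance_prior_lines <- function(par, variant, sd_upper, indent = "  ") {
  tau <- sub("^sigma", "tau", par)
  if (variant == "main") {
    c(sprintf("%s%s ~ dunif(0, %s)", indent, par, format(sd_upper)),
      sprintf("%s%s <- pow(%s, -2)", indent, tau, par))
  } else {
    c(sprintf("%s%s ~ dgamma(var.ig.a, var.ig.b)", indent, tau),
      sprintf("%s%s <- pow(%s, -0.5)", indent, par, tau))
  }
}

# P = 1 degenerates the inverse-Wishart to an inverse-gamma: Sigma ~ IW(D, d)
# in one dimension is 1/Sigma ~ Gamma(d/2, rate = D/2).
pollutant_block <- function(P, trend, variant, sd_upper, ar_lag, include_Y) {
  latent <- if (trend == "none") "mu" else "theta"
  lines <- c("  # pollutant component", "  for (p in 1:P) {",
             variance_prior_lines("sigma.y[p]", variant, sd_upper, indent = "    "),
             "  }")
  if (include_Y) {
    lines <- c(lines,
               "  for (p in 1:P) {",
               "    for (t in 1:T) { Y[t,p] ~ dnorm(mu[t,p], tau.y[p]) }",
               "  }")
  }
  if (P == 1L) {
    lines <- c(lines,
      sprintf("  for (j in 1:%d) { %s[j,1] ~ dnorm(0, Itheta0[1,1]) }", ar_lag, latent),
      sprintf("  for (t in %d:T) { %s[t,1] ~ dnorm(%s[t-%d,1], Omega[1,1]) }",
              ar_lag + 1L, latent, latent, ar_lag),
      "  Omega[1,1] ~ dgamma(dfw/2, Dscale[1,1]/2)",
      "  Sigma[1,1] <- 1/Omega[1,1]")
  } else {
    lines <- c(lines,
      sprintf("  for (j in 1:%d) { %s[j,1:P] ~ dmnorm(zeroP[1:P], Itheta0[1:P,1:P]) }",
              ar_lag, latent),
      sprintf("  for (t in %d:T) { %s[t,1:P] ~ dmnorm(%s[t-%d,1:P], Omega[1:P,1:P]) }",
              ar_lag + 1L, latent, latent, ar_lag),
      "  Omega ~ dwish(Dscale[1:P,1:P], dfw)",
      "  Sigma[1:P,1:P] <- inverse(Omega)")
  }
  if (trend == "covariates") {
    lines <- c(lines,
      "  for (p in 1:P) {",
      "    g0[p] ~ dnorm(0, prec.coef)",
      "    for (j in 1:4) { g[p,j] ~ dnorm(0, prec.coef) }",
      "  }",
      "  for (t in 1:T) {",
      "    for (p in 1:P) {",
      paste0("      mu[t,p] <- g0[p] + g[p,1]*xtemp[t] + g[p,2]*xtemp2[t]",
             " + g[p,3]*xrhum[t] + g[p,4]*xrhum2[t] + theta[t,p]"),
      "    }",
      "  }")
  } else if (trend == "intercept") {
    lines <- c(lines,
      "  for (p in 1:P) { g0[p] ~ dnorm(0, prec.coef) }",
      "  for (t in 1:T) {",
      "    for (p in 1:P) { mu[t,p] <- g0[p] + theta[t,p] }",
      "  }")
  }
  lines
}

health_prior_block <- function(n_splines, holiday, overdispersion, variant,
                               sd_upper, eps_range) {
  lines <- c("  # health component",
             "  beta0 ~ dnorm(0, prec.coef)",
             "  for (p in 1:P) { beta[p] ~ dnorm(0, prec.beta) }")
  if (holiday) lines <- c(lines, "  delta ~ dnorm(0, prec.coef)")
  for (i in seq_len(n_splines)) {
    lines <- c(lines,
      sprintf("  alpha[%d] ~ dnorm(0, prec.coef)", i),
      sprintf("  tau.b[%d] ~ dgamma(spl.a, spl.b)", i),
      sprintf("  for (k in 1:K%d) { b%d[k] ~ dnorm(0, tau.b[%d]) }", i, i, i))
  }
  if (overdispersion) {
    lines <- c(lines,
      variance_prior_lines("sigma.eps", variant, sd_upper),
      sprintf("  for (t in %s) { eps[t] ~ dnorm(0, tau.eps) }", eps_range))
  }
  lines
}

health_terms <- function(n_splines, holiday, overdispersion, t = "t") {
  terms <- character(0)
  for (i in seq_len(n_splines)) {
    terms <- c(terms,
               sprintf(" + alpha[%d]*xs%d[%s] + inprod(Z%d[%s,1:K%d], b%d[1:K%d])",
                       i, i, t, i, t, i, i, i))
  }
  if (holiday) terms <- c(terms, sprintf(" + delta*hol[%s]", t))
  if (overdispersion) terms <- c(terms, sprintf(" + eps[%s]", t))
  paste(terms, collapse = "")
}

build_joint_model <- function(P, trend, health_priors, include_O, include_Y,
                              health_lag, ar_lag, n_splines, holiday,
                              overdispersion, variant, sd_upper) {
  lines <- c("model {",
             pollutant_block(P, trend, variant, sd_upper, ar_lag, include_Y))
  ostart <- health_lag + 1L
  if (health_priors) {
    lines <- c(lines,
      health_prior_block(n_splines, holiday, overdispersion, variant, sd_upper,
                         eps_range = sprintf("%d:T", ostart)))
  }
  if (include_O) {
    lines <- c(lines,
      "  for (p in 1:P) { bs[p] <- beta[p] * ysd[p] }",
      "  cbeta <- inprod(beta[1:P], ymean[1:P])",
      sprintf("  for (t in %d:T) {", ostart),
      sprintf("    log(lambda[t]) <- beta0 + cbeta + inprod(bs[1:P], mu[%s,1:P])%s",
              if (health_lag > 0) sprintf("t-%d", health_lag) else "t",
              health_terms(n_splines, holiday, overdispersion)),
      "    O[t] ~ dpois(Ect * lambda[t])",
      "  }")
  }
  paste(c(lines, "}"), collapse = "\n")
}

build_me_model <- function(n_splines, holiday, overdispersion, variant,
                           sd_upper, include_O = TRUE) {
  lines <- c("model {",
    health_prior_block(n_splines, holiday, overdispersion, variant, sd_upper,
                       eps_range = "1:Tm"))
  if (include_O) {
    lines <- c(lines,
      "  for (t in 1:Tm) {",
      sprintf("    log(lambda[t]) <- beta0 + inprod(beta[1:P], X[t,1:P])%s",
              health_terms(n_splines, holiday, overdispersion)),
      "    O[t] ~ dpois(Ect * lambda[t])",
      "  }")
  }
  paste(c(lines, "}"), collapse = "\n")
}

# Spline design pieces for the health model: covariates are affinely scaled
# to [0, 1] before knot placement and basis construction (pure numerical
# conditioning -- the radial cubic basis on raw day indices 1..T would span
# ~1e8); basis columns are sample-centered for identifiability next to the
# intercept. The fitted smooth is unchanged as a function of the covariate.
spline_design <- function(x, K, name) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) abort(paste0("confounder '", name, "' is constant"))
  xs <- (x - rng[1]) / diff(rng)
  kn <- spline_knots(xs, K)
  list(name = name, K = K, knots_scaled = kn,
       knots = kn * diff(rng) + rng[1],
       xs = xs - mean(xs),
       Z = tps_basis_centered(xs, kn))
}

build_spline_designs <- function(splines, covariates) {
  if (is.null(splines) || length(splines) == 0L) return(list())
  cov_x <- list(time = covariates$time_index,
                temperature = covariates$temperature,
                rel_humidity = covariates$rel_humidity)
  out <- list()
  for (i in seq_along(splines)) {
    nm <- names(splines)[i]
    if (!nm %in% names(cov_x)) abort(paste0("unknown confounder '", nm, "'"))
    x <- cov_x[[nm]]
    if (anyNA(x)) abort(paste0("confounder '", nm, "' has missing values"))
    out[[nm]] <- spline_design(x, splines[[i]], nm)
  }
  out
}

# Rename raw JAGS columns to pollutant-labelled terms. JAGS drops the index
# on length-one vector monitors ("beta" instead of "beta[1]"), so bare names
# are canonicalized first.
relabel_draws <- function(nms, pollutants) {
  P <- length(pollutants)
  for (bare in c("beta", "sigma.y", "g0", "alpha", "tau.b")) {
    nms <- sub(paste0("^", gsub(".", "\\.", bare, fixed = TRUE), "$"),
               paste0(bare, "[1]"), nms)
  }
  nms <- sub("^Sigma$", "Sigma[1,1]", nms)
  nms <- sub("^beta\\[(\\d+)\\]$", "beta_\\1", nms)
  nms <- sub("^sigma\\.y\\[(\\d+)\\]$", "sigma_proc_\\1", nms)
  for (i in seq_len(P)) {
    nms <- sub(paste0("^beta_", i, "$"), paste0("beta_", pollutants[i]), nms)
    nms <- sub(paste0("^sigma_proc_", i, "$"),
               paste0("sigma_proc_", pollutants[i]), nms)
  }
  sub("^sigma\\.eps$", "sigma_eps", nms)
}

jags_inits <- function(n_chains, seed, base) {
  lapply(seq_len(n_chains), function(c_) {
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = (seed + 1000L * c_) %% 2147483646L + 1L))
  })
}

# Pool an mcmc.list into one draws matrix (chains stacked).
pool_chains <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

# Extract "mu[t,p]"-style columns from a pooled draws matrix into an array
# [draw, T, P].
extract_mu_array <- function(pooled, T_, P, prefix = "mu") {
  cols <- matrix(NA_integer_, T_, P)
  cn <- colnames(pooled)
  for (t in seq_len(T_)) for (p in seq_len(P)) {
    cols[t, p] <- match(sprintf("%s[%d,%d]", prefix, t, p), cn)
  }
  if (anyNA(cols)) abort("latent concentration draws not found in monitor set")
  arr <- array(pooled[, as.vector(cols)], dim = c(nrow(pooled), T_, P))
  arr
}
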