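#' Fit the joint two-component hierarchical model (H2Mjoint)
#'
#' Jointly estimates the latent-concentration pollutant model and the Poisson
#' health model in one posterior: measured concentrations are treated as noisy
#' versions of latent standardized concentrations whose residual temporal
#' effects follow a driftless multivariate random walk, and the daily counts
#' are Poisson with a log-linear effect of the (lagged, back-transformed)
#' latent concentrations. Missing concentration cells are treated as unknowns
#' and imputed by the sampler through the cross-pollutant correlation and the
#' temporal dependence. Because the two components live in a single graph,
#' uncertainty on concentrations feeds forward into the health effects and
#' information from the outcome feeds back into the concentrations.
#'
#' @param data A `poll_panel` tibble (see [read_panel()] / [as_panel()]).
#' @param pollutants Pollutant columns to model; default all.
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param health_lag Exposure lag (days) in the health model; default 1.
#' @param ar_lag Temporal lag of the latent autoregression; default 1.
#' @param confounder_splines Named integer vector of knot counts for smoothed
#'   confounders, any of `time`, `temperature`, `rel_humidity`; `NULL` for
#'   none. Default `c(time = 6, temperature = 3, rel_humidity = 3)`.
#' @param holiday Include the workday/weekend-holiday term? Default `TRUE`.
#' @param overdispersion Include the daily Normal overdispersion random
#'   effect? Default `TRUE`.
#' @param pollutant_covariates Include linear + quadratic temperature and
#'   humidity terms in the latent pollutant means? Default `TRUE`; set
#'   `FALSE` for covariate-free data such as the simulation design (the
#'   latent process then carries the whole mean).
#' @param center_covariates Center the covariate columns (and their squares)
#'   before sampling? A pure reparameterization that sharply improves mixing;
#'   set `FALSE` to sample on the raw measured scale.
#' @param expected_count Expected daily count E; default the mean observed
#'   count over the study period.
#' @param likelihood `"full"` (default), `"pollutant"` (the outcome is cut
#'   out: health coefficients return their priors, useful for prior audits),
#'   or `"none"` (prior-only run: every parameter returns its prior).
#' @param monitor_mu Keep posterior draws of the latent concentrations
#'   (standardized scale)? Needed by [fit_h2m()] internally.
#' @param monitor_loglam Keep per-day log relative-risk draws (needed by
#'   [dic()])?
#' @param monitor_imputed Keep draws of the imputed missing measurements and
#'   the latent mean at those cells?
#' @param quiet Suppress JAGS progress output.
#' @param engine `"auto"` (default), `"jags"` or `"gibbs"`. The native Gibbs
#'   engine covers the simulation-form model only (no covariate trend,
#'   splines, holiday term or overdispersion; lag-1 latent walk) and mixes
#'   the collinear coefficient block an order of magnitude faster per second
#'   than the general graph sampler; `"auto"` selects it whenever the
#'   requested model qualifies and no JAGS-only monitor is requested.
#'
#' @return An object of class `h2m_fit`; see [tidy.h2m_fit()],
#'   [report_effects()], [report_process_variance()].
#' @export
fit_h2mjoint <- function(data, pollutants = NULL, priors = prior_config(),
                         mcmc = mcmc_config(), health_lag = 1L, ar_lag = 1L,
                         confounder_splines = c(time = 6, temperature = 3,
                                                rel_humidity = 3),
                         holiday = TRUE, overdispersion = TRUE,
                         pollutant_covariates = TRUE,
                         center_covariates = TRUE, expected_count = NULL,
                         likelihood = c("full", "pollutant", "none"),
                         monitor_mu = FALSE, monitor_loglam = FALSE,
                         monitor_imputed = FALSE, quiet = TRUE,
                         engine = c("auto", "jags", "gibbs")) {
  likelihood <- match.arg(likelihood)
  fit_joint_impl(data, pollutants, priors, mcmc, health_lag, ar_lag,
                 confounder_splines, holiday, overdispersion,
                 pollutant_covariates, expected_count,
                 center_covariates = center_covariates,
                 include_O = likelihood == "full",
                 include_Y = likelihood != "none",
                 health_priors = TRUE, likelihood = likelihood,
                 monitor_mu = monitor_mu, monitor_loglam = monitor_loglam,
                 monitor_imputed = monitor_imputed, quiet = quiet,
                 model_label = "h2mjoint", engine = match.arg(engine))
}

fit_joint_impl <- function(data, pollutants, priors, mcmc, health_lag, ar_lag,
                           confounder_splines, holiday, overdispersion,
                           pollutant_covariates, expected_count,
                           include_O, include_Y, health_priors, likelihood,
                           monitor_mu, monitor_loglam, monitor_imputed,
                           quiet, model_label, center_covariates = TRUE,
                           engine = "auto") {
  t0 <- Sys.time()
  pollutants <- pollutants %||% pollutant_names(data)
  P <- length(pollutants)
  T_ <- nrow(data)
  if (T_ <= max(ar_lag, health_lag)) abort("too few days for the requested lags")
  if (include_O && anyNA(data$count)) abort("counts must be complete")

  std <- standardize_pollutants(data, pollutants)
  scaling <- pollutant_scaling(std)
  Y <- as.matrix(std[pollutants])
  E <- expected_count %||% mean(data$count, na.rm = TRUE)
  if (E <= 0) abort("'expected_count' must be positive")

  dfw <- priors$iw_df %||% P
  Dscale <- priors$iw_scale %||% default_iw_scale(data, pollutants, d = dfw)
  trend <- if (pollutant_covariates) "covariates" else "none"
  designs <- if (include_O || health_priors) {
    build_spline_designs(confounder_splines, data)
  } else list()
  ns <- length(designs)

  gibbs_ok <- trend == "none" && ns == 0L && !holiday && !overdispersion &&
    ar_lag == 1L && include_Y && !monitor_imputed && !monitor_loglam
  if (engine == "auto") engine <- if (gibbs_ok) "gibbs" else "jags"
  if (engine == "gibbs" && !gibbs_ok) {
    abort("the native Gibbs engine only covers the simulation-form model")
  }
  if (engine == "gibbs") {
    gres <- run_gibbs_joint(Ystd = Y, O = data$count, E = E,
                            ysd = scaling$scale, ymean = scaling$center,
                            Dscale = unname(Dscale), dfw = dfw,
                            health_lag = health_lag, priors = priors,
                            mcmc = mcmc, include_outcome = include_O,
                            monitor_mu = monitor_mu)
    samples <- coda::as.mcmc.list(lapply(gres$chains, function(ch) {
      colnames(ch) <- relabel_draws(colnames(ch), pollutants)
      coda::mcmc(ch)
    }))
    kept_days <- seq.int(health_lag + 1L, T_)
    return(new_h2m_fit(
      model = model_label, samples = samples, pollutants = pollutants,
      scaling = scaling, iqr = pollutant_iqr(data, pollutants),
      health_lag = health_lag, ar_lag = ar_lag, E = E,
      outcome = list(counts = data$count, E = E, kept_days = kept_days),
      priors = priors, mcmc = mcmc,
      options = list(likelihood = likelihood, trend = trend,
                     holiday = holiday, overdispersion = overdispersion,
                     splines = list(), engine = "gibbs",
                     accept_th = gres$accept_th,
                     n_missing = sum(is.na(Y))),
      loglam = NULL, mu_draws = gres$mu_draws, imputed = NULL,
      runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  model_str <- build_joint_model(P = P, trend = trend,
                                 health_priors = health_priors,
                                 include_O = include_O, include_Y = include_Y,
                                 health_lag = health_lag, ar_lag = ar_lag,
                                 n_splines = ns, holiday = holiday,
                                 overdispersion = overdispersion,
                                 variant = priors$variant,
                                 sd_upper = priors$sd_upper)

  jdata <- list(T = T_, P = P,
                Itheta0 = diag(1 / 100, P),
                Dscale = unname(Dscale), dfw = dfw,
                prec.coef = 1 / priors$coef_sd^2,
                prec.beta = 1 / priors$beta_sd^2)
  if (P > 1L) jdata$zeroP <- rep(0, P)
  if (include_Y) jdata$Y <- unname(Y)
  if (priors$variant == "sensitivity") {
    jdata$var.ig.a <- priors$var_ig_a; jdata$var.ig.b <- priors$var_ig_b
  }
  if (trend == "covariates") {
    if (anyNA(data$temperature) || anyNA(data$rel_humidity)) {
      abort("temperature and rel_humidity must be complete to use pollutant covariates")
    }
    if (center_covariates) {
      # centered linear and quadratic columns: a reparameterization of the
      # same quadratic trend that removes the near-collinearity with the
      # intercept and the random-walk level, without changing the fitted
      # latent mean as a function of the covariates
      xt <- data$temperature - mean(data$temperature)
      xr <- data$rel_humidity - mean(data$rel_humidity)
      jdata$xtemp <- xt; jdata$xtemp2 <- xt^2 - mean(xt^2)
      jdata$xrhum <- xr; jdata$xrhum2 <- xr^2 - mean(xr^2)
    } else {
      jdata$xtemp <- data$temperature; jdata$xtemp2 <- data$temperature^2
      jdata$xrhum <- data$rel_humidity; jdata$xrhum2 <- data$rel_humidity^2
    }
  }
  if (health_priors && ns > 0) {
    jdata$spl.a <- priors$spline_gamma_a; jdata$spl.b <- priors$spline_gamma_b
    for (i in seq_len(ns)) {
      jdata[[paste0("K", i)]] <- designs[[i]]$K
      jdata[[paste0("xs", i)]] <- designs[[i]]$xs
      jdata[[paste0("Z", i)]] <- designs[[i]]$Z
    }
  }
  if (include_O) {
    jdata$O <- data$count
    jdata$Ect <- E
    jdata$ysd <- scaling$scale
    jdata$ymean <- scaling$center
    if (holiday) jdata$hol <- as.numeric(data$holiday)
  } else if (health_priors && holiday) {
    # delta still needs its prior; no data required
  }

  base_inits <- list(beta0 = if (include_O) log(max(mean(data$count, na.rm = TRUE), 1) / E) else 0,
                     beta = rep(0, P))
  latent_name <- if (trend == "none") "mu" else "theta"
  base_inits[[latent_name]] <- matrix(0, T_, P)
  if (P > 1L) base_inits$Omega <- diag(P) else base_inits$Omega <- matrix(1, 1, 1)
  if (priors$variant == "main") {
    base_inits$sigma.y <- rep(0.5, P)
    if (overdispersion && health_priors) base_inits$sigma.eps <- 0.05
  } else {
    base_inits$tau.y <- rep(4, P)
    if (overdispersion && health_priors) base_inits$tau.eps <- 400
  }
  if (trend == "covariates") { base_inits$g0 <- rep(0, P); base_inits$g <- matrix(0, P, 4) }
  if (health_priors && holiday) base_inits$delta <- 0
  if (health_priors && ns > 0) {
    base_inits$alpha <- rep(0, ns); base_inits$tau.b <- rep(10, ns)
    for (i in seq_len(ns)) base_inits[[paste0("b", i)]] <- rep(0, designs[[i]]$K)
  }
  if (health_priors && overdispersion) {
    ostart <- health_lag + 1L
    eps0 <- rep(NA_real_, T_); eps0[ostart:T_] <- 0
    base_inits$eps <- eps0
  }

  monitors <- c("sigma.y", "Sigma")
  if (health_priors) monitors <- c("beta0", "beta", monitors)
  if (trend == "covariates") monitors <- c(monitors, "g0", "g")
  if (health_priors && holiday) monitors <- c(monitors, "delta")
  if (health_priors && ns > 0) monitors <- c(monitors, "alpha", "tau.b")
  if (health_priors && overdispersion) monitors <- c(monitors, "sigma.eps")
  extra <- character(0)
  if (monitor_mu) extra <- c(extra, "mu")
  if (monitor_loglam && include_O) extra <- c(extra, "lambda")
  imputed_cells <- NULL
  if (monitor_imputed && include_Y && anyNA(Y)) {
    idx <- which(is.na(Y), arr.ind = TRUE)
    imputed_cells <- tibble::tibble(day = idx[, 1], pollutant = pollutants[idx[, 2]])
    extra <- c(extra,
               sprintf("Y[%d,%d]", idx[, 1], idx[, 2]),
               sprintf("mu[%d,%d]", idx[, 1], idx[, 2]))
  }

  res <- run_jags(model_str, jdata,
                  inits = jags_inits(mcmc$n_chains, mcmc$seed, base_inits),
                  monitors = c(monitors, extra), mcmc = mcmc, quiet = quiet)

  samples <- lapply(res$samples, function(ch) {
    keep <- !grepl("^(mu|lambda|Y)\\[", colnames(ch))
    ch2 <- ch[, keep, drop = FALSE]
    colnames(ch2) <- relabel_draws(colnames(ch2), pollutants)
    ch2
  })
  samples <- coda::as.mcmc.list(lapply(samples, coda::mcmc))

  kept_days <- seq.int(health_lag + 1L, T_)
  loglam <- NULL
  if (monitor_loglam && include_O) {
    lam_cols <- sprintf("lambda[%d]", kept_days)
    loglam <- log(res$pooled[, lam_cols, drop = FALSE])
  }
  mu_draws <- if (monitor_mu) extract_mu_array(res$pooled, T_, P) else NULL
  imputed <- NULL
  if (!is.null(imputed_cells)) {
    ycols <- sprintf("Y[%d,%d]", imputed_cells$day,
                     match(imputed_cells$pollutant, pollutants))
    mcols <- sprintf("mu[%d,%d]", imputed_cells$day,
                     match(imputed_cells$pollutant, pollutants))
    imputed <- list(cells = imputed_cells,
                    Y = res$pooled[, ycols, drop = FALSE],
                    mu = res$pooled[, mcols, drop = FALSE])
  }

  new_h2m_fit(model = model_label, samples = samples, pollutants = pollutants,
              scaling = scaling, iqr = pollutant_iqr(data, pollutants),
              health_lag = health_lag, ar_lag = ar_lag, E = E,
              outcome = list(counts = data$count, E = E, kept_days = kept_days),
              priors = priors, mcmc = mcmc,
              options = list(likelihood = likelihood, trend = trend,
                             holiday = holiday, overdispersion = overdispersion,
                             splines = lapply(designs, function(d)
                               d[c("name", "K", "knots")]),
                             n_missing = sum(is.na(Y))),
              loglam = loglam, mu_draws = mu_draws, imputed = imputed,
              runtime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Fit the plug-in measured-concentration Poisson model (ME)
#'
#' The conventional single-stage time-series model: daily counts are Poisson
#' with a log-linear effect of the lagged *measured* concentrations, ignoring
#' measurement error. Days whose lagged exposure (any pollutant) or count is
#' missing are dropped (complete-case analysis). Optional confounder splines,
#' holiday term and overdispersion random effect as in [fit_h2mjoint()].
#'
#' @inheritParams fit_h2mjoint
#' @return An `h2m_fit` object.
#' @export
fit_me <- function(data, pollutants = NULL, priors = prior_config(),
                   mcmc = mcmc_config(), health_lag = 1L,
                   confounder_splines = c(time = 6, temperature = 3,
                                          rel_humidity = 3),
                   holiday = TRUE, overdispersion = TRUE,
                   expected_count = NULL,
                   likelihood = c("full", "none"),
                   monitor_loglam = FALSE, quiet = TRUE) {
  likelihood <- match.arg(likelihood)
  t0 <- Sys.time()
  pollutants <- pollutants %||% pollutant_names(data)
  P <- length(pollutants)
  T_ <- nrow(data)
  if (T_ <= health_lag) abort("too few days for the requested lag")
  Yorig <- as.matrix(data[pollutants])
  E <- expected_count %||% mean(data$count, na.rm = TRUE)

  # complete-case rows: day t kept iff count observed and every pollutant
  # measured at t - health_lag
  days <- seq.int(health_lag + 1L, T_)
  X <- Yorig[days - health_lag, , drop = FALSE]
  ok <- stats::complete.cases(X) & !is.na(data$count[days])
  kept_days <- days[ok]
  X <- X[ok, , drop = FALSE]
  O <- data$count[kept_days]
  Tm <- length(kept_days)
  if (Tm < P + 2L) abort("too few complete-case days")

  kept_cov <- data[kept_days, , drop = FALSE]
  designs <- build_spline_designs(confounder_splines, kept_cov)
  ns <- length(designs)

  model_str <- build_me_model(n_splines = ns, holiday = holiday,
                              overdispersion = overdispersion,
                              variant = priors$variant,
                              sd_upper = priors$sd_upper,
                              include_O = likelihood == "full")
  jdata <- list(Tm = Tm, P = P,
                prec.coef = 1 / priors$coef_sd^2,
                prec.beta = 1 / priors$beta_sd^2)
  if (likelihood == "full") {
    jdata$X <- unname(X); jdata$O <- O; jdata$Ect <- E
    if (holiday) jdata$hol <- as.numeric(kept_cov$holiday)
  }
  if (priors$variant == "sensitivity") {
    jdata$var.ig.a <- priors$var_ig_a; jdata$var.ig.b <- priors$var_ig_b
  }
  if (ns > 0) {
    jdata$spl.a <- priors$spline_gamma_a; jdata$spl.b <- priors$spline_gamma_b
    for (i in seq_len(ns)) {
      jdata[[paste0("K", i)]] <- designs[[i]]$K
      jdata[[paste0("xs", i)]] <- designs[[i]]$xs
      jdata[[paste0("Z", i)]] <- designs[[i]]$Z
    }
  }
  base_inits <- list(beta0 = if (likelihood == "full") log(max(mean(O), 1) / E) else 0,
                     beta = rep(0, P))
  if (holiday) base_inits$delta <- 0
  if (ns > 0) {
    base_inits$alpha <- rep(0, ns); base_inits$tau.b <- rep(10, ns)
    for (i in seq_len(ns)) base_inits[[paste0("b", i)]] <- rep(0, designs[[i]]$K)
  }
  if (overdispersion) {
    if (priors$variant == "main") base_inits$sigma.eps <- 0.05
    else base_inits$tau.eps <- 400
    base_inits$eps <- rep(0, Tm)
  }

  monitors <- c("beta0", "beta")
  if (holiday) monitors <- c(monitors, "delta")
  if (ns > 0) monitors <- c(monitors, "alpha", "tau.b")
  if (overdispersion) monitors <- c(monitors, "sigma.eps")
  if (monitor_loglam && likelihood == "full") monitors <- c(monitors, "lambda")

  res <- run_jags(model_str, jdata,
                  inits = jags_inits(mcmc$n_chains, mcmc$seed, base_inits),
                  monitors = monitors, mcmc = mcmc, quiet = quiet)
  samples <- lapply(res$samples, function(ch) {
    keep <- !grepl("^lambda\\[", colnames(ch))
    ch2 <- ch[, keep, drop = FALSE]
    colnames(ch2) <- relabel_draws(colnames(ch2), pollutants)
    ch2
  })
  samples <- coda::as.mcmc.list(lapply(samples, coda::mcmc))
  loglam <- NULL
  if (monitor_loglam && likelihood == "full") {
    loglam <- log(res$pooled[, sprintf("lambda[%d]", seq_len(Tm)), drop = FALSE])
  }

  new_h2m_fit(model = "me", samples = samples, pollutants = pollutants,
              scaling = NULL, iqr = pollutant_iqr(data, pollutants),
              health_lag = health_lag, ar_lag = NA_integer_, E = E,
              outcome = list(counts = data$count, E = E, kept_days = kept_days),
              priors = priors, mcmc = mcmc,
              options = list(likelihood = likelihood, holiday = holiday,
                             overdispersion = overdispersion,
                             splines = lapply(designs, function(d)
                               d[c("name", "K", "knots")]),
                             n_dropped = as.integer(T_ - health_lag - Tm)),
              loglam = loglam, mu_draws = NULL, imputed = NULL,
              runtime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Fit the two-stage cut model (H2M)
#'
#' Stage 1 fits the pollutant component alone (no outcome data). Stage 2
#' samples the health component while drawing, at every iteration, one
#' stage-1 posterior realization of the latent concentrations — so exposure
#' uncertainty feeds *forward* into the health effects, but no information
#' flows back from the outcome to the concentrations (the "cut").
#'
#' @inheritParams fit_h2mjoint
#' @return An `h2m_fit` object. Health-component draws come from the stage-2
#'   cut sampler; pollutant-component draws (process sds, innovation
#'   covariance) from stage 1.
#' @export
fit_h2m <- function(data, pollutants = NULL, priors = prior_config(),
                    mcmc = mcmc_config(), health_lag = 1L, ar_lag = 1L,
                    confounder_splines = c(time = 6, temperature = 3,
                                           rel_humidity = 3),
                    holiday = TRUE, overdispersion = TRUE,
                    pollutant_covariates = TRUE, center_covariates = TRUE,
                    expected_count = NULL,
                    monitor_loglam = FALSE, quiet = TRUE) {
  t0 <- Sys.time()
  pollutants <- pollutants %||% pollutant_names(data)

  stage1 <- fit_joint_impl(data, pollutants, priors, mcmc, health_lag, ar_lag,
                           confounder_splines = NULL, holiday = FALSE,
                           overdispersion = FALSE,
                           pollutant_covariates = pollutant_covariates,
                           expected_count = expected_count,
                           include_O = FALSE, include_Y = TRUE,
                           health_priors = FALSE, likelihood = "pollutant",
                           monitor_mu = TRUE, monitor_loglam = FALSE,
                           monitor_imputed = FALSE, quiet = quiet,
                           model_label = "h2m_stage1",
                           center_covariates = center_covariates)

  # stage-1 latent concentrations, back-transformed to original units
  scaling <- stage1$scaling
  mu_arr <- stage1$mu_draws
  for (p in seq_along(pollutants)) {
    mu_arr[, , p] <- mu_arr[, , p] * scaling$scale[p] + scaling$center[p]
  }

  E <- expected_count %||% mean(data$count, na.rm = TRUE)
  designs <- build_spline_designs(confounder_splines, data)
  stage2 <- run_cut_sampler(mu_arr, counts = data$count, E = E,
                            health_lag = health_lag,
                            designs = designs,
                            holiday_vec = if (holiday) as.numeric(data$holiday) else NULL,
                            overdispersion = overdispersion,
                            priors = priors, mcmc = mcmc,
                            pollutants = pollutants,
                            monitor_loglam = monitor_loglam)

  # merge: health draws (stage 2) + pollutant draws (stage 1), per chain;
  # stage 1 may carry prior draws of the health block -- drop those
  s1 <- lapply(stage1$samples, function(ch) {
    m <- as.matrix(ch)
    m[, !grepl("^(beta0$|beta_)", colnames(m)), drop = FALSE]
  })
  samples <- coda::as.mcmc.list(lapply(seq_along(stage2$chains), function(c_) {
    coda::mcmc(cbind(stage2$chains[[c_]], s1[[c_]]))
  }))

  kept_days <- seq.int(health_lag + 1L, nrow(data))
  new_h2m_fit(model = "h2m", samples = samples, pollutants = pollutants,
              scaling = scaling, iqr = pollutant_iqr(data, pollutants),
              health_lag = health_lag, ar_lag = ar_lag, E = E,
              outcome = list(counts = data$count, E = E, kept_days = kept_days),
              priors = priors, mcmc = mcmc,
              options = list(likelihood = "cut", trend = stage1$options$trend,
                             holiday = holiday, overdispersion = overdispersion,
                             splines = lapply(designs, function(d)
                               d[c("name", "K", "knots")]),
                             n_missing = stage1$options$n_missing,
                             stage2_accept = stage2$accept),
              loglam = stage2$loglam, mu_draws = NULL, imputed = NULL,
              runtime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

new_h2m_fit <- function(model, samples, pollutants, scaling, iqr, health_lag,
                        ar_lag, E, outcome, priors, mcmc, options, loglam,
                        mu_draws, imputed, runtime) {
  diag_tbl <- diagnostics_table(samples)
  structure(list(model = model, samples = samples, pollutants = pollutants,
                 scaling = scaling, iqr = iqr, health_lag = health_lag,
                 ar_lag = ar_lag, E = E, outcome = outcome, priors = priors,
                 mcmc = mcmc, options = options, loglam = loglam,
                 mu_draws = mu_draws, imputed = imputed,
                 diagnostics = diag_tbl, runtime = runtime),
            class = "h2m_fit")
}

#' @export
print.h2m_fit <- function(x, ...) {
  cat("<h2m_fit> model:", x$model,
      "| pollutants:", paste(x$pollutants, collapse = ", "),
      "| chains:", length(x$samples),
      "x", nrow(x$samples[[1]]), "draws\n")
  cat("max Gelman-Rubin:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
      "| MC-error rule satisfied:",
      sum(x$diagnostics$mc_ok), "/", nrow(x$diagnostics), "parameters\n")
  invisible(x)
}

# Internal: compile + adapt + burn + sample a JAGS model.
run_jags <- function(model_str, jdata, inits, monitors, mcmc, quiet = TRUE) {
  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = jdata,
                            inits = inits, n.chains = mcmc$n_chains,
                            n.adapt = mcmc$n_adapt, quiet = quiet)
    if (mcmc$n_burn > 0) stats::update(jm, mcmc$n_burn,
                                       progress.bar = if (quiet) "none" else "text")
    rjags::coda.samples(jm, variable.names = unique(monitors),
                        n.iter = mcmc$n_keep * mcmc$thin, thin = mcmc$thin,
                        progress.bar = if (quiet) "none" else "text")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()
  list(samples = samples, pooled = pool_chains(samples))
}
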