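# Shared fixtures: tiny panels and short chain settings, built in code.

make_test_panel <- function(n_days = 100, n_pollutants = 2, seed = 42,
                            corr = NULL, beta_true = NULL, meas_var = 0.1,
                            expected_count = 37) {
  if (is.null(corr) && n_pollutants == 2) {
    corr <- matrix(c(1, 0.7, 0.7, 1), 2, 2)
  }
  if (is.null(beta_true)) {
    beta_true <- rep(0, n_pollutants)
    beta_true[seq_len(min(2, n_pollutants))] <- c(0.3, -0.3)[seq_len(min(2, n_pollutants))]
  }
  cfg <- sim_config(n_days = n_days, n_pollutants = n_pollutants, corr = corr,
                    meas_var = meas_var, beta_true = beta_true,
                    expected_count = expected_count, n_reps = 1)
  simulate_panel(cfg, seed = seed)
}

# add covariates + mask some cells, for fits that use the full model surface
decorate_panel <- function(panel, n_missing = 0, seed = 1) {
  set.seed(seed)
  T_ <- nrow(panel)
  panel$temperature <- round(10 + 6 * sin(2 * pi * seq_len(T_) / 365) + rnorm(T_, 0, 2), 1)
  panel$rel_humidity <- round(pmin(98, pmax(40, 75 + rnorm(T_, 0, 8))), 1)
  if (n_missing > 0) {
    polls <- pollutant_names(panel)
    cells <- cbind(sample(seq_len(T_), n_missing, replace = TRUE),
                   sample(seq_along(polls), n_missing, replace = TRUE))
    cells <- cells[!duplicated(cells), , drop = FALSE]
    for (k in seq_len(nrow(cells))) {
      panel[[polls[cells[k, 2]]]][cells[k, 1]] <- NA
    }
  }
  panel
}

fast_mcmc <- function(n_burn = 500, n_keep = 500, n_chains = 1, seed = 1,
                      n_adapt = 200) {
  mcmc_config(n_burn = n_burn, n_keep = n_keep, n_chains = n_chains,
              seed = seed, n_adapt = n_adapt)
}

# build an h2m_fit-shaped object from given draw matrices (for reporting tests)
fake_fit <- function(draws, pollutants, iqr_values) {
  samples <- coda::as.mcmc.list(list(coda::mcmc(draws)))
  structure(list(model = "h2mjoint", samples = samples,
                 pollutants = pollutants,
                 scaling = NULL,
                 iqr = tibble::tibble(pollutant = pollutants, iqr = iqr_values),
                 health_lag = 1L, ar_lag = 1L, E = 37,
                 outcome = list(counts = rep(37, 10), E = 37, kept_days = 2:10),
                 priors = prior_config(), mcmc = fast_mcmc(),
                 options = list(), loglam = NULL, mu_draws = NULL,
                 imputed = NULL,
                 diagnostics = tibble::tibble(term = colnames(draws),
                                              rhat = NA_real_, mc_se = 0,
                                              mc_ok = TRUE),
                 runtime = 0),
            class = "h2m_fit")
}
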