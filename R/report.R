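#' Effect table: percent increase per IQR change
#'
#' For each pollutant, the observed-data interquartile range and the posterior
#' mean and equal-tailed 95% credible interval of the percent increase in the
#' event rate for an IQR change in concentration. The transformation
#' (exp(beta * IQR) - 1) * 100 is applied per posterior draw and then
#' summarized, so concentration uncertainty propagates into the interval.
#'
#' @param fit An `h2m_fit`.
#' @param data Optional panel to recompute IQRs from; defaults to the IQRs
#'   recorded at fit time.
#' @return A tibble with columns `pollutant`, `iqr`, `pct_increase_mean`,
#'   `pct_lo95`, `pct_hi95`.
#' @export
report_effects <- function(fit, data = NULL) {
  iqr <- if (is.null(data)) fit$iqr else pollutant_iqr(data, fit$pollutants)
  pooled <- pool_chains(fit$samples)
  rows <- lapply(seq_along(fit$pollutants), function(i) {
    p <- fit$pollutants[i]
    cn <- paste0("beta_", p)
    if (!cn %in% colnames(pooled)) abort(paste0("no posterior draws for ", cn))
    pct <- percent_increase(pooled[, cn], iqr$iqr[iqr$pollutant == p])
    q <- quantile(pct, c(.025, .975), names = FALSE)
    tibble::tibble(pollutant = p, iqr = iqr$iqr[iqr$pollutant == p],
                   pct_increase_mean = mean(pct), pct_lo95 = q[1], pct_hi95 = q[2])
  })
  dplyr::bind_rows(rows)
}

#' Process-variance table
#'
#' Posterior mean and equal-tailed 95% credible interval of each pollutant's
#' process variance sigma_p^2 (standardized scale), computed draw-wise from
#' the process-sd chains. Small values mean the latent model explains the
#' measured series almost entirely; large values point to residual
#' unexplained variability.
#'
#' @param fit An `h2m_fit` with process-sd draws (H2Mjoint or H2M).
#' @return A tibble with columns `pollutant`, `var_mean`, `var_lo95`,
#'   `var_hi95`.
#' @export
report_process_variance <- function(fit) {
  pooled <- pool_chains(fit$samples)
  rows <- lapply(fit$pollutants, function(p) {
    cn <- paste0("sigma_proc_", p)
    if (!cn %in% colnames(pooled)) abort(paste0("no posterior draws for ", cn))
    v <- pooled[, cn]^2
    q <- quantile(v, c(.025, .975), names = FALSE)
    tibble::tibble(pollutant = p, var_mean = mean(v), var_lo95 = q[1], var_hi95 = q[2])
  })
  dplyr::bind_rows(rows)
}

#' Single-pollutant model suite
#'
#' Fits the joint model once per pollutant with that pollutant alone (the
#' conventional single-pollutant analysis) and assembles the per-pollutant
#' effect tables. The same code path as the multi-pollutant fit is used, with
#' P = 1.
#'
#' @param data A `poll_panel`.
#' @param pollutants Pollutants to loop over; default all.
#' @param priors,mcmc,... Passed to [fit_h2mjoint()].
#' @return A tibble as in [report_effects()], one row per pollutant, with the
#'   fitted models in the `"fits"` attribute.
#' @export
run_single_pollutant_suite <- function(data, pollutants = NULL,
                                       priors = prior_config(),
                                       mcmc = mcmc_config(), ...) {
  pollutants <- pollutants %||% pollutant_names(data)
  fits <- list()
  rows <- lapply(seq_along(pollutants), function(i) {
    mc <- mcmc; mc$seed <- as.integer(derive_seed(mcmc$seed, i) %% 2147483647)
    fit <- fit_h2mjoint(data, pollutants = pollutants[i], priors = priors,
                        mcmc = mc, ...)
    fits[[pollutants[i]]] <<- fit
    report_effects(fit)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}

#' Write a JSON run manifest
#'
#' Records what is needed to re-run a fit or study bit-identically with the
#' same software version: configurations, seed, model options (including knot
#' locations, prior variant and imputed-cell count where applicable) and a
#' diagnostics summary.
#'
#' @param x An `h2m_fit` or `mp_study`.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  m <- run_manifest(x)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
run_manifest <- function(x) {
  if (inherits(x, "h2m_fit")) {
    list(command = paste0("fit_", x$model),
         seed = x$mcmc$seed,
         mcmc = unclass(x$mcmc),
         priors = prior_manifest(x$priors),
         options = manifest_options(x$options),
         pollutants = x$pollutants,
         expected_count = x$E,
         diagnostics = list(
           max_rhat = if (all(is.na(x$diagnostics$rhat))) NULL
                      else max(x$diagnostics$rhat, na.rm = TRUE),
           mc_error_rule_pass = sum(x$diagnostics$mc_ok),
           n_parameters = nrow(x$diagnostics)),
         runtime_s = x$runtime,
         version = as.character(utils::packageVersion("multipoll")))
  } else if (inherits(x, "mp_study")) {
    cfg <- unclass(x$config); cfg$corr <- NULL
    list(command = "run_study", seed = x$seed,
         config = cfg,
         corr = apply(x$config$corr, 1, function(r) r, simplify = FALSE),
         mcmc = unclass(x$mcmc),
         estimators = unique(x$results$estimator),
         n_failures = nrow(x$failures),
         version = as.character(utils::packageVersion("multipoll")))
  } else abort("no manifest method for this object")
}

prior_manifest <- function(p) {
  out <- unclass(p)
  if (!is.null(out$iw_scale)) out$iw_scale <- as.vector(out$iw_scale)
  out
}

manifest_options <- function(o) {
  o$splines <- lapply(o$splines, function(s)
    list(name = s$name, K = s$K, knots = as.numeric(s$knots)))
  o
}
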