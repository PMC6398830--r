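# Study-driver tests use cheap deterministic "estimators" so that the metric
# arithmetic is isolated from MCMC behaviour.

oracle_estimator <- function(width = 0.4) {
  function(panel, truth, mcmc, seed) {
    tibble::tibble(term = paste0("beta_poll", seq_along(truth$beta)),
                   estimate = truth$beta,
                   conf.low = truth$beta - width / 2,
                   conf.high = truth$beta + width / 2)
  }
}

shifted_estimator <- function(shift = 1) {
  function(panel, truth, mcmc, seed) {
    tibble::tibble(term = paste0("beta_poll", seq_along(truth$beta)),
                   estimate = truth$beta + shift,
                   conf.low = truth$beta + shift - 0.01,
                   conf.high = truth$beta + shift + 0.01)
  }
}

test_that("an oracle estimator scores zero bias and full coverage", {
  cfg <- sim_config(n_days = 30, n_pollutants = 2, corr = diag(2),
                    beta_true = c(0.2, 0), n_reps = 4)
  st <- run_study(cfg, estimators = list(oracle = oracle_estimator(0.4)),
                  seed = 2)
  m <- st$metrics
  expect_equal(m$bias, rep(0, 2))
  expect_equal(m$ci95_coverage, rep(100, 2))
  expect_equal(m$ci95_width, rep(0.4, 2))
  expect_equal(m$rmse, rep(0, 2))
  expect_identical(m$n_reps_used, rep(4L, 2))
})

test_that("a truth-plus-one estimator has bias exactly one and zero coverage", {
  cfg <- sim_config(n_days = 30, n_pollutants = 2, corr = diag(2),
                    beta_true = c(0.2, 0), n_reps = 3)
  st <- run_study(cfg, estimators = list(shift = shifted_estimator(1)), seed = 3)
  expect_equal(st$metrics$bias, rep(1, 2))
  expect_equal(st$metrics$ci95_coverage, rep(0, 2))
  expect_equal(st$metrics$rmse, rep(1, 2))
  expect_equal(st$metrics$mse, rep(1, 2))
})

test_that("metrics equal a hand computation from the persisted replicate file", {
  # a noisy but deterministic estimator: truth + f(rep seed)
  noisy <- function(panel, truth, mcmc, seed) {
    delta <- (seq_along(truth$beta) * as.numeric(seed)) %% 7 / 100
    tibble::tibble(term = paste0("beta_poll", seq_along(truth$beta)),
                   estimate = truth$beta + delta,
                   conf.low = truth$beta + delta - 0.03,
                   conf.high = truth$beta + delta + 0.03)
  }
  cfg <- sim_config(n_days = 30, n_pollutants = 2, corr = diag(2),
                    beta_true = c(0.2, 0), n_reps = 3)
  out <- file.path(tempdir(), "microstudy")
  st <- run_study(cfg, estimators = list(noisy = noisy), seed = 11,
                  out_dir = out)
  reps <- readr::read_csv(file.path(out, "replicates.csv"),
                          show_col_types = FALSE)
  for (tm in unique(reps$term)) {
    sub <- reps[reps$term == tm, ]
    row <- st$metrics[st$metrics$term == tm, ]
    expect_equal(row$bias, mean(sub$estimate - sub$truth))
    expect_equal(row$variance, var(sub$estimate))
    expect_equal(row$rmse, sqrt(mean((sub$estimate - sub$truth)^2)))
    expect_equal(row$ci95_width, mean(sub$conf.high - sub$conf.low))
    expect_equal(row$ci95_coverage,
                 100 * mean(sub$conf.low <= sub$truth & sub$truth <= sub$conf.high))
  }
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_equal(man$config$n_reps, 3)
})

test_that("replicate seeds derive deterministically from the master seed", {
  cfg <- sim_config(n_days = 25, n_pollutants = 2, corr = diag(2),
                    beta_true = c(0, 0), n_reps = 2)
  grab <- function(...) {
    run_study(cfg, estimators = list(o = oracle_estimator()), seed = 9)$results
  }
  expect_identical(grab(), grab())
})

test_that("failing replicates are excluded and excess failure aborts", {
  flaky <- function(panel, truth, mcmc, seed) {
    if (attr(panel, "truth")$mu[1, 1] > -Inf && panel$count[1] %% 2 == 0) {
      stop("sampler divergence")
    }
    oracle_estimator()(panel, truth, mcmc, seed)
  }
  cfg <- sim_config(n_days = 30, n_pollutants = 2, corr = diag(2),
                    beta_true = c(0.2, 0), n_reps = 40)
  # about half the replicates fail -> abort
  expect_error(run_study(cfg, estimators = list(flaky = flaky), seed = 4),
               "aborting")

  one_bad <- local({
    calls <- 0L
    function(panel, truth, mcmc, seed) {
      calls <<- calls + 1L
      if (calls == 2L) stop("boom")
      oracle_estimator()(panel, truth, mcmc, seed)
    }
  })
  cfg$n_reps <- 30L
  st <- run_study(cfg, estimators = list(ob = one_bad), seed = 4)
  expect_identical(nrow(st$failures), 1L)
  expect_identical(unique(st$metrics$n_reps_used), 29L)
})
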