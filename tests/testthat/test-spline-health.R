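test_that("knots sit at equally spaced quantiles", {
  x <- 1:100
  expect_equal(spline_knots(x, 3),
               quantile(x, c(.25, .5, .75), names = FALSE))
  expect_equal(spline_knots(x, 1), median(x))
  expect_error(spline_knots(rep(2, 50), 3), class = "multipoll_degenerate_error")
  kn <- spline_knots(rep(1:4, each = 25), 3)  # heavy ties still separate
  expect_true(all(diff(kn) > 0))
})

test_that("thin-plate spline evaluation matches its definition", {
  sp <- spline_spec("temperature", knots = 2, alpha = 0, b = 1)
  expect_equal(spline_eval(sp, 2), 0)  # basis vanishes at its knot
  sp_id <- spline_spec("time", knots = c(1, 5), alpha = 1, b = c(0, 0))
  x <- seq(-3, 8, by = 0.5)
  expect_equal(spline_eval(sp_id, x), x)

  set.seed(21)
  kn <- sort(rnorm(4)); a <- rnorm(1); b <- rnorm(4)
  sp_r <- spline_spec("rel_humidity", kn, a, b)
  xs <- rnorm(10)
  oracle <- vapply(xs, function(x) a * x + sum(b * abs(x - kn)^3), numeric(1))
  expect_equal(spline_eval(sp_r, xs), oracle, tolerance = 1e-12)

  expect_error(spline_spec("t", knots = c(2, 1)), "increasing")
})

test_that("health linear predictor matches a double-loop oracle and lag semantics", {
  set.seed(22)
  T_ <- 12; P <- 2
  cov <- tibble::tibble(temperature = rnorm(T_, 10, 4),
                        rel_humidity = rnorm(T_, 70, 5),
                        time_index = seq_len(T_),
                        holiday = rep(c(FALSE, FALSE, TRUE), 4))
  mu <- matrix(rnorm(T_ * P), T_, P)
  sp <- spline_spec("temperature", knots = c(8, 12), alpha = 0.02,
                    b = c(1e-3, -5e-4))
  state <- list(beta0 = 0.5, beta = c(0.2, -0.1), splines = list(sp),
                delta = 0.05, eps = rnorm(T_, 0, 0.05), health_lag = 1L)
  lp <- health_linpred(cov, mu, state)
  expect_true(is.na(lp[1]))
  oracle <- numeric(T_)
  for (t in 2:T_) {
    oracle[t] <- state$beta0 +
      sum(state$beta * mu[t - 1, ]) +
      0.02 * cov$temperature[t] +
      sum(c(1e-3, -5e-4) * abs(cov$temperature[t] - c(8, 12))^3) +
      0.05 * cov$holiday[t] + state$eps[t]
  }
  expect_equal(lp[2:T_], oracle[2:T_], tolerance = 1e-12)

  # shifting the exposure by one day shifts its contribution by one day
  state0 <- list(beta0 = 0, beta = c(0.2, 0), splines = list(), delta = 0,
                 eps = 0, health_lag = 1L)
  lp1 <- health_linpred(cov, mu, state0)
  mu_shift <- rbind(mu[-1, ], 0)
  lp2 <- health_linpred(cov, mu_shift, state0)
  expect_equal(lp2[2:(T_ - 1)], lp1[3:T_], tolerance = 1e-12)
})

test_that("with no confounders the predictor reduces to the simulation form", {
  set.seed(23)
  T_ <- 10
  cov <- tibble::tibble(temperature = rnorm(T_), rel_humidity = rnorm(T_),
                        time_index = 1:T_, holiday = rep(FALSE, T_))
  mu <- matrix(rnorm(T_ * 3), T_, 3)
  state <- list(beta0 = 1, beta = c(0.2, 0.2, -0.2), splines = list(),
                delta = 0, eps = 0, health_lag = 1L)
  lp <- health_linpred(cov, mu, state)
  expect_equal(lp[2:T_],
               1 + drop(mu[1:(T_ - 1), ] %*% c(0.2, 0.2, -0.2)),
               tolerance = 1e-12)
})

test_that("Poisson outcome log likelihood has its closed forms", {
  # zero count: term is -rate
  expect_equal(outcome_loglik(0L, log(2.5), E = 1), -2.5, tolerance = 1e-12)

  set.seed(24)
  O <- rpois(8, 30); lp <- rnorm(8, 0, 0.2); E <- 37
  oracle <- sum(dpois(O[3:8], E * exp(lp[3:8]), log = TRUE))
  expect_equal(outcome_loglik(O, lp, E, start = 2L), oracle, tolerance = 1e-12)

  # doubling E changes each term by O log 2 - E exp(lp)
  d <- outcome_loglik(O, lp, 2 * E) - outcome_loglik(O, lp, E)
  expect_equal(d, sum(O * log(2) - E * exp(lp)), tolerance = 1e-10)

  expect_error(outcome_loglik(c(-1L, 2L), c(0, 0), 1), "negative")
  expect_error(outcome_loglik(1L, 0, 0), "positive")
})

test_that("percent increase per IQR has its identities", {
  expect_equal(percent_increase(0, 5), 0)
  expect_equal(percent_increase(log(2) / 7.4, 7.4), 100, tolerance = 1e-10)
  # monotone increasing in beta for fixed iqr
  b <- seq(-0.3, 0.3, by = 0.05)
  expect_true(all(diff(percent_increase(b, 2)) > 0))
  expect_error(percent_increase(0.1, 0), "positive")
})

test_that("the overdispersed Poisson has marginal variance above its mean", {
  set.seed(25)
  n <- 40000; E <- 37
  lp <- 0.1 + rnorm(n, 0, 0.15)   # fixed mean plus overdispersion effect
  O <- rpois(n, E * exp(lp))
  expect_gt(var(O), mean(O) * 1.2)
})
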