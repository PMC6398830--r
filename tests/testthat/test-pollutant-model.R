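test_that("latent pollutant mean matches a scalar double-loop oracle", {
  set.seed(7)
  T_ <- 9; P <- 3
  cov <- tibble::tibble(temperature = rnorm(T_, 10, 5),
                        rel_humidity = rnorm(T_, 75, 8))
  gamma <- matrix(rnorm(P * 5, 0, 0.3), P, 5)
  theta <- matrix(rnorm(T_ * P), T_, P)

  oracle <- matrix(0, T_, P)
  for (t in seq_len(T_)) for (p in seq_len(P)) {
    oracle[t, p] <- gamma[p, 1] + gamma[p, 2] * cov$temperature[t] +
      gamma[p, 3] * cov$temperature[t]^2 + gamma[p, 4] * cov$rel_humidity[t] +
      gamma[p, 5] * cov$rel_humidity[t]^2 + theta[t, p]
  }
  expect_equal(pollutant_mean(cov, gamma, theta), oracle, tolerance = 1e-12)

  expect_equal(pollutant_mean(cov, matrix(0, P, 5), matrix(0, T_, P)),
               matrix(0, T_, P))
  g1 <- matrix(0, P, 5); g1[, 1] <- 1
  expect_equal(pollutant_mean(cov, g1, matrix(0, T_, P)), matrix(1, T_, P))
  expect_error(pollutant_mean(cov, gamma[, 1:4], theta), "5 columns")
})

test_that("measurement log likelihood sums observed cells only", {
  expect_equal(measurement_loglik(matrix(0.5), matrix(0.5), 1),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(8)
  Y <- matrix(rnorm(6), 3, 2); mu <- matrix(rnorm(6), 3, 2)
  s <- c(0.7, 1.3)
  oracle <- 0
  for (t in 1:3) for (p in 1:2) {
    oracle <- oracle + dnorm(Y[t, p], mu[t, p], s[p], log = TRUE)
  }
  expect_equal(measurement_loglik(Y, mu, s), oracle, tolerance = 1e-12)

  # masking one cell removes exactly that cell's term
  Y2 <- Y; Y2[2, 1] <- NA
  expect_equal(measurement_loglik(Y, mu, s) - measurement_loglik(Y2, mu, s),
               dnorm(Y[2, 1], mu[2, 1], s[1], log = TRUE), tolerance = 1e-12)

  expect_error(measurement_loglik(Y, mu, c(1, -1)), "positive")
})

test_that("autoregressive residual log likelihood has the stated closed forms", {
  # constant rows, identity covariance: each transition term is -(P/2) log 2pi
  T_ <- 5; P <- 3
  theta <- matrix(0, T_, P)
  val <- ar_residual_loglik(theta, diag(P), lag = 1)
  expected <- (T_ - 1) * (-P / 2 * log(2 * pi)) +
    P * dnorm(0, 0, 10, log = TRUE)
  expect_equal(val, expected, tolerance = 1e-12)

  # P = 1 reduces to the univariate random-walk log likelihood
  set.seed(11)
  th1 <- matrix(cumsum(rnorm(12)), ncol = 1)
  s2 <- 0.8
  oracle <- sum(dnorm(diff(drop(th1)), 0, sqrt(s2), log = TRUE)) +
    dnorm(th1[1], 0, 10, log = TRUE)
  expect_equal(ar_residual_loglik(th1, matrix(s2), lag = 1), oracle,
               tolerance = 1e-12)

  # relabeling pollutants together with the covariance leaves the value alone
  set.seed(12)
  th <- matrix(rnorm(8 * 3), 8, 3)
  A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  perm <- c(3, 1, 2)
  expect_equal(ar_residual_loglik(th, A),
               ar_residual_loglik(th[, perm], A[perm, perm]), tolerance = 1e-10)

  expect_error(ar_residual_loglik(th, matrix(c(1, 2, 2, 1), 2)), "positive-definite")
  expect_error(ar_residual_loglik(th[1, , drop = FALSE], diag(3)), "more rows")
})

test_that("joint pollutant density decomposes into measurement + AR + priors", {
  # brute-force monolithic oracle on a small instance
  set.seed(13)
  T_ <- 6; P <- 2
  theta <- matrix(rnorm(T_ * P), T_, P)
  Sig <- matrix(c(1, 0.4, 0.4, 1.2), 2)
  mu <- theta + 0.3  # intercept-only latent mean
  Y <- mu + matrix(rnorm(T_ * P, sd = 0.4), T_, P)
  Y[4, 2] <- NA
  s <- c(0.4, 0.4)

  mono <- 0
  for (t in seq_len(T_)) for (p in seq_len(P)) {
    if (!is.na(Y[t, p])) mono <- mono + dnorm(Y[t, p], mu[t, p], s[p], log = TRUE)
  }
  Rch <- chol(Sig)
  for (t in 2:T_) {
    d <- theta[t, ] - theta[t - 1, ]
    z <- backsolve(Rch, d, transpose = TRUE)
    mono <- mono - 0.5 * (P * log(2 * pi) + 2 * sum(log(diag(Rch))) + sum(z^2))
  }
  mono <- mono + sum(dnorm(theta[1, ], 0, 10, log = TRUE))

  expect_equal(measurement_loglik(Y, mu, s) + ar_residual_loglik(theta, Sig),
               mono, tolerance = 1e-12)
})

test_that("with diagonal covariance and intercept-only means pollutants decouple", {
  set.seed(14)
  T_ <- 7
  theta <- matrix(rnorm(T_ * 2), T_, 2)
  Y <- theta + matrix(rnorm(T_ * 2, sd = 0.3), T_, 2)
  s <- c(0.3, 0.5)
  joint <- measurement_loglik(Y, theta, s) +
    ar_residual_loglik(theta, diag(c(0.8, 1.4)))
  separate <- sum(vapply(1:2, function(p) {
    measurement_loglik(Y[, p, drop = FALSE], theta[, p, drop = FALSE], s[p]) +
      ar_residual_loglik(theta[, p, drop = FALSE],
                         matrix(c(0.8, 1.4)[p]), lag = 1)
  }, numeric(1)))
  expect_equal(joint, separate, tolerance = 1e-10)
})

test_that("back-transformation restores original units", {
  sc <- tibble::tibble(pollutant = c("a", "b"), center = c(10, -1), scale = c(2, 0.5))
  mu_std <- matrix(c(0, 1.5, 1, -2), 2, 2)
  out <- backtransform_mu(mu_std, sc)
  expect_equal(out[1, 1], 10)       # mu_std = 0 -> center
  expect_equal(out[2, 1], 13)       # 1.5 * 2 + 10
  expect_equal(out[, 2], c(-0.5, -2))

  panel <- make_test_panel(n_days = 30, seed = 5)
  std <- standardize_pollutants(panel)
  mu2 <- as.matrix(std[pollutant_names(panel)])
  back <- backtransform_mu(mu2, pollutant_scaling(std))
  expect_equal(back, as.matrix(panel[pollutant_names(panel)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(backtransform_mu(mu_std, tibble::tibble(pollutant = "a")),
               "standardization")
})
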