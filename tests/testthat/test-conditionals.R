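# Each conditional is checked twice: against the stated closed-form special
# cases, and against midpoint-quadrature integration of prior x likelihood.

test_that("W conditional: prior recovery, conjugate update, flat-prior limit", {
  prior <- prior_config()
  # no likelihood contribution when the transcript column is zero
  d0 <- toy_data(n = 3, T = matrix(0, 3, 1), A = NULL)
  st0 <- toy_state(d0, I = matrix(rnorm(3), 3, 1))
  fc0 <- cond_w(1, st0, d0, prior)
  expect_equal(fc0$mean, 1)
  expect_equal(fc0$var, 1)

  # n=1, T=1, residual 2, tau_w=1 -> N(1.5, 0.5)
  d1 <- toy_data(n = 1, T = matrix(1, 1, 1), A = NULL)
  st1 <- toy_state(d1, I0 = 0, I = matrix(2, 1, 1))
  fc1 <- cond_w(1, st1, d1, prior)
  expect_equal(fc1$mean, 1.5)
  expect_equal(fc1$var, 0.5)

  # flat-prior limit: data take over
  fc_flat <- cond_w(1, st1, d1, prior_config(tau_w = 1e10))
  expect_equal(fc_flat$mean, 2, tolerance = 1e-8)
  expect_equal(fc_flat$var, 1, tolerance = 1e-8)
})

test_that("D conditional: prior recovery, conjugate update, spike-slab degeneracy", {
  prior <- prior_config()
  dA0 <- toy_data(n = 3, A = rep(0, 3))
  stA0 <- toy_state(dA0, I = matrix(rnorm(3), 3, 1))
  fcA0 <- cond_d(1, stA0, dA0, prior)
  expect_equal(fcA0$mean, 0)
  expect_equal(fcA0$var, 1)

  # n=2, A=(1,0), residuals (2, .) -> N(1, 0.5)
  d2 <- toy_data(n = 2, A = c(1, 0))
  st2 <- toy_state(d2, I = matrix(c(2, -7), 2, 1))
  fc2 <- cond_d(1, st2, d2, prior)
  expect_equal(fc2$mean, 1)
  expect_equal(fc2$var, 0.5)

  # theta = 1: the mixture degenerates to the normal-family conditional
  fc_ss <- cond_d(1, st2, d2, prior_config(family = "spike_slab", theta = 1))
  expect_equal(fc_ss$mean, fc2$mean)
  expect_equal(fc_ss$var, fc2$var)
  expect_equal(fc_ss$pip, 1)
})

test_that("I0 conditional: edge cases and flat-prior limit", {
  prior <- prior_config()
  d <- toy_data(n = 4, A = NULL)
  st <- toy_state(d, I = matrix(c(1, 2, 3, 4), 4, 1))
  fc <- cond_i0(1, st, d, prior_config(tau_i0 = 1e10))
  expect_equal(fc$mean, 2.5, tolerance = 1e-8)  # average residual
  fc1 <- cond_i0(1, st, d, prior)
  expect_equal(fc1$var, 1 / 5)
  expect_equal(fc1$mean, 10 / 5)
})

test_that("Z conditional: truncated prior recovery, base normal, degenerate bounds", {
  prior <- prior_config()
  # latent column all zeros -> truncated prior
  dz <- toy_data(n = 3, A = NULL)
  stz <- toy_state(dz, I = matrix(0, 3, 1))
  fcz <- cond_z(1, 1, stz, dz, prior)
  expect_equal(fcz$mean, 1)
  expect_equal(fcz$var, 1)
  expect_equal(fcz$lower, 0.5)
  expect_equal(fcz$upper, 2)

  # n=1, I=1, partial residual 2, sigma2=1, tau_z=1 -> base N(1.5, 0.5)
  d1 <- toy_data(n = 1, P = matrix(c(2, 0), 1, 2), A = NULL)
  st1 <- toy_state(d1, I = matrix(1, 1, 1),
                   Z = matrix(c(0, 0), 1, 2))
  fc1 <- cond_z(1, 1, st1, d1, prior)
  expect_equal(fc1$mean, 1.5)
  expect_equal(fc1$var, 0.5)

  # degenerate bounds give a point mass
  d1$bounds <- list(lower = 1, upper = 1)
  expect_equal(isofactor:::rtnorm(5, 3, 2, 1, 1), rep(1, 5))

  # off-support entries are a contract violation
  doff <- iso_dataset(matrix(1:4, 2, 2), matrix(c(1, 0), 1, 2))
  expect_error(cond_z(1, 2, toy_state(doff), doff, prior), "off the mask")
})

test_that("noise conditional: conjugate inverse-gamma arithmetic", {
  prior <- prior_config()
  d <- toy_data(n = 2, P = matrix(c(1, -1, 0, 0), 2, 2), A = NULL)
  st <- toy_state(d, I = matrix(0, 2, 1), Z = matrix(0, 1, 2))
  fc <- cond_noise(1, st, d, prior)
  expect_equal(fc$shape, 2)
  expect_equal(fc$rate, 2)

  # zero residuals keep the prior rate; smaller RSS, smaller posterior mean
  fc0 <- cond_noise(2, st, d, prior)
  expect_equal(fc0$rate, 1)
  expect_lt(fc0$rate / (fc0$shape - 1), fc$rate / (fc$shape - 1))
})

test_that("I-row conditional: prior recovery and conjugate update", {
  prior <- prior_config()
  # Z all zero: posterior equals the structural prior
  d <- toy_data(n = 2, T = matrix(c(1, 2), 2, 1), A = c(1, 0))
  st <- toy_state(d, I0 = 0.5, W = 1, D = 2, Z = matrix(0, 1, 2))
  fc <- cond_i_row(1, st, d, prior)
  expect_equal(fc$mean, 0.5 + 1 + 2)
  expect_equal(fc$cov[1, 1], 1)

  # 1 isoform, 1 peptide, Z=1, sigma2=1, prior mean 0, P=2 -> N(1, 0.5)
  d1 <- iso_dataset(matrix(2, 1, 1), matrix(1, 1, 1))
  d1$bounds <- list(lower = 1, upper = 1)
  st1 <- list(I0 = 0, Z = matrix(1, 1, 1), I = matrix(0, 1, 1), sigma2 = 1)
  fc1 <- cond_i_row(1, st1, d1, prior)
  expect_equal(fc1$mean, 1)
  expect_equal(fc1$cov[1, 1], 0.5)
})

test_that("I-row precision is symmetric positive-definite for random blocks", {
  set.seed(7)
  for (rep in 1:10) {
    q <- sample(2:4, 1)
    r <- q + sample(1:4, 1)
    mask <- matrix(rbinom(q * r, 1, 0.5), q, r)
    mask[cbind(seq_len(q), seq_len(q))] <- 1
    d <- iso_dataset(matrix(rnorm(3 * r, 5), 3, r), mask)
    st <- list(I0 = rep(0, q), Z = mask * runif(q * r, 0.5, 1.5),
               I = matrix(0, 3, q), sigma2 = runif(r, 0.5, 2))
    ci <- isofactor:::cond_i_all(st, d)
    Lambda <- t(ci$chol_prec) %*% ci$chol_prec
    expect_equal(Lambda, t(Lambda), tolerance = 1e-12)
    expect_true(all(eigen(Lambda, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("every conditional matches grid integration on single-isoform toys", {
  prior <- prior_config(tau_w = 0.8, tau_d = 1.3, tau_z = 0.9, tau_i0 = 2)
  Tm <- matrix(c(1.2, -0.4), 2, 1)
  A <- c(1, 0)
  P <- matrix(c(2.2, 1.4, 4.1, 3.0), 2, 2)
  d <- toy_data(n = 2, r = 2, T = Tm, A = A, P = P,
                bounds = list(lower = 0.4, upper = 2.5))
  st <- list(I0 = 0.3, W = 1.1, D = 0.5, Z = matrix(c(0.9, 1.2), 1, 2),
             I = matrix(c(4.0, 2.8), 2, 1), sigma2 = c(0.8, 1.4))

  # W | rest
  fc <- cond_w(1, st, d, prior)
  or <- grid_posterior(function(w) {
    dnorm(w, 1, sqrt(0.8), log = TRUE) +
      sum(dnorm(st$I[, 1], st$I0 + Tm[, 1] * w + A * st$D, 1, log = TRUE))
  }, fc$mean - 8 * sqrt(fc$var), fc$mean + 8 * sqrt(fc$var))
  expect_equal(fc$mean, or$mean, tolerance = 1e-6)
  expect_equal(fc$var, or$var, tolerance = 1e-6)

  # D | rest
  fc <- cond_d(1, st, d, prior)
  or <- grid_posterior(function(dd) {
    dnorm(dd, 0, sqrt(1.3), log = TRUE) +
      sum(dnorm(st$I[, 1], st$I0 + Tm[, 1] * st$W + A * dd, 1, log = TRUE))
  }, fc$mean - 8 * sqrt(fc$var), fc$mean + 8 * sqrt(fc$var))
  expect_equal(fc$mean, or$mean, tolerance = 1e-6)
  expect_equal(fc$var, or$var, tolerance = 1e-6)

  # I0 | rest
  fc <- cond_i0(1, st, d, prior)
  or <- grid_posterior(function(i0) {
    dnorm(i0, 0, sqrt(2), log = TRUE) +
      sum(dnorm(st$I[, 1], i0 + Tm[, 1] * st$W + A * st$D, 1, log = TRUE))
  }, fc$mean - 8 * sqrt(fc$var), fc$mean + 8 * sqrt(fc$var))
  expect_equal(fc$mean, or$mean, tolerance = 1e-6)
  expect_equal(fc$var, or$var, tolerance = 1e-6)

  # Z | rest (truncated): moments of the truncated conditional
  fc <- cond_z(1, 1, st, d, prior)
  or <- grid_posterior(function(z) {
    isofactor:::dtnorm(z, 1, sqrt(0.9), 0.4, 2.5, log = TRUE) +
      sum(dnorm(P[, 1], st$I[, 1] * z, sqrt(st$sigma2[1]), log = TRUE))
  }, 0.4, 2.5)
  mt <- tnorm_moments(fc$mean, sqrt(fc$var), fc$lower, fc$upper)
  expect_lt(abs(mt$mean - or$mean), 1e-6)
  expect_lt(abs(mt$var - or$var), 1e-6)

  # I_i | rest (q = 1): scalar case against the grid
  fc <- cond_i_row(1, st, d, prior)
  mu1 <- st$I0 + Tm[1, 1] * st$W + A[1] * st$D
  or <- grid_posterior(function(ii) {
    dnorm(ii, mu1, 1, log = TRUE) +
      sum(dnorm(P[1, ], ii * st$Z[1, ], sqrt(st$sigma2), log = TRUE))
  }, fc$mean - 8 * sqrt(fc$cov[1, 1]), fc$mean + 8 * sqrt(fc$cov[1, 1]))
  expect_equal(unname(fc$mean), or$mean, tolerance = 1e-6)
  expect_equal(fc$cov[1, 1], or$var, tolerance = 1e-6)

  # sigma2_k | rest: grid over the precision, whose gamma posterior has
  # exponentially decaying tails (the sigma2 scale truncates too slowly)
  pr2 <- prior_config(noise_a0 = 2.5, noise_b0 = 1.2)
  fc <- cond_noise(1, st, d, pr2)
  or <- grid_posterior(function(lam) {
    (2.5 - 1) * log(lam) - 1.2 * lam +
      sum(dnorm(P[, 1], st$I %*% st$Z[, 1], sqrt(1 / lam), log = TRUE))
  }, 1e-6, 30, step = 1e-3)
  expect_equal(fc$shape / fc$rate, or$mean, tolerance = 1e-6)
  expect_equal(fc$shape / fc$rate^2, or$var, tolerance = 1e-6)
})
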