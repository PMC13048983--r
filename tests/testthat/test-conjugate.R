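test_that("emission log-density matches the Gaussian form and normalizes", {
  expect_equal(emission_log_density(0, 0, 1), -0.918938533204673, tolerance = 1e-10)
  expect_equal(emission_log_density(1, 0, 1), -0.918938533204673 - 0.5,
               tolerance = 1e-10)
  expect_error(emission_log_density(0, 0, -1), "positive")
  # exp of the log-density integrates to 1 for arbitrary parameters
  for (p in list(c(0, 1), c(2.3, 0.41), c(-1.7, 9))) {
    I <- integrate(function(x) exp(emission_log_density(x, p[1], p[2])),
                   -Inf, Inf)
    expect_equal(I$value, 1, tolerance = 1e-6)
  }
})

test_that("emission posterior update reduces to the prior and matches closed forms", {
  prior <- blink_prior()
  # state 2 holds no data: prior recovered exactly
  set.seed(1)
  res <- sample_emission_posterior(rep(1L, 5), rnorm(5), prior)
  expect_equal(res$update$nu_hat[2], 1)
  expect_equal(res$update$m_hat[2], 0)
  expect_equal(res$update$a_hat[2], 1)
  expect_equal(res$update$b_hat[2], 1)
  # 5 bins in state 1 with nu = 1: nu_hat = 6, a_hat = 2.5 + a
  expect_equal(res$update$nu_hat[1], 6)
  expect_equal(res$update$a_hat[1], 3.5)
  z <- c(1.2, -0.4, 0.3, 0.8, -1.1)
  res2 <- sample_emission_posterior(rep(1L, 5), z, prior)
  expect_equal(res2$update$m_hat[1], sum(z) / 6)
  expect_equal(res2$update$b_hat[1],
               0.5 * (sum(z^2) - 6 * (sum(z) / 6)^2) + 1)
  expect_gt(res2$update$b_hat[1], 0)
})

test_that("emission posterior draws concentrate on the data-generating mean", {
  prior <- blink_prior()
  set.seed(2)
  z <- rnorm(1e4, mean = 2, sd = 1)
  labels <- rep(1L, 1e4)
  draws <- replicate(100, sample_emission_posterior(labels, z, prior)$mu[1])
  expect_equal(mean(draws), 2, tolerance = 0.05 / 2)
})

test_that("transition posterior counts transitions into columns correctly", {
  prior <- blink_prior()
  # labels ON, ON, OFF, ON: one ON->ON, one ON->OFF, one OFF->ON
  set.seed(3)
  res <- sample_transition_posterior(c(1L, 1L, 2L, 1L), prior)
  expect_equal(res$beta_hat, matrix(c(2, 2, 2, 1), 2))
  expect_equal(colSums(res$A), c(1, 1))
  # no transitions observed: posterior equals the prior Dirichlet
  res1 <- sample_transition_posterior(c(1L, 1L), prior)
  expect_equal(res1$beta_hat, matrix(c(2, 1, 1, 1), 2))
  # Dirichlet moment oracle: empirical column mean matches beta_hat column
  draws <- replicate(1e4,
    sample_transition_posterior(c(1L, 1L, 2L, 1L), prior)$A[1, 1])
  m <- 2 / 4 # beta_hat[, 1] = (2, 2)
  se <- sqrt(m * (1 - m) / (4 + 1)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - m), 3 * se)
})

test_that("initial-state posterior is the one-hot Dirichlet update", {
  prior <- blink_prior()
  set.seed(4)
  res <- sample_initial_posterior(1L, prior)
  expect_equal(res$alpha_hat, c(2, 1))
  expect_equal(sum(res$pi), 1)
  draws <- replicate(5e3, sample_initial_posterior(1L, prior)$pi[1])
  expect_equal(mean(draws), 2 / 3, tolerance = 0.03)
  # prior dominance: a large symmetric prior swamps the single observation
  big <- blink_prior(alpha = c(500, 500))
  draws2 <- replicate(2e3, sample_initial_posterior(1L, big)$pi[1])
  expect_equal(mean(draws2), 0.5, tolerance = 0.02)
})

test_that("sampled-posterior density ratios match the complete-data joint", {
  # On random small instances the log-ratio of the conjugate posterior at two
  # parameter values must equal the log-ratio of the full joint with all
  # other blocks held fixed, to near machine precision.
  prior <- blink_prior()
  set.seed(5)
  for (rep in 1:10) {
    N <- sample(5:20, 1)
    z <- rnorm(N)
    labels <- sample(1:2, N, replace = TRUE)
    pars1 <- random_params()
    pars2 <- random_params()

    # emission block: Gauss-Gamma posterior
    up <- sample_emission_posterior(labels, z, prior)$update
    post_ratio <- sum(vapply(1:2, function(k)
      log_gauss_gamma(pars1$mu[k], pars1$lam[k], up$m_hat[k], up$nu_hat[k],
                      up$a_hat[k], up$b_hat[k]) -
      log_gauss_gamma(pars2$mu[k], pars2$lam[k], up$m_hat[k], up$nu_hat[k],
                      up$a_hat[k], up$b_hat[k]), numeric(1)))
    joint_ratio <-
      complete_log_joint(z, labels, pars1$mu, pars1$lam, pars1$A, pars1$pi, prior) -
      complete_log_joint(z, labels, pars2$mu, pars2$lam, pars1$A, pars1$pi, prior)
    expect_equal(post_ratio, joint_ratio, tolerance = 1e-9)

    # transition block: per-column Dirichlet posterior
    bh <- sample_transition_posterior(labels, prior)$beta_hat
    post_ratio_A <- sum(vapply(1:2, function(l)
      log_dirichlet(pars1$A[, l], bh[, l]) -
      log_dirichlet(pars2$A[, l], bh[, l]), numeric(1)))
    joint_ratio_A <-
      complete_log_joint(z, labels, pars1$mu, pars1$lam, pars1$A, pars1$pi, prior) -
      complete_log_joint(z, labels, pars1$mu, pars1$lam, pars2$A, pars1$pi, prior)
    expect_equal(post_ratio_A, joint_ratio_A, tolerance = 1e-9)

    # initial block: Dirichlet posterior
    ah <- sample_initial_posterior(labels[1], prior)$alpha_hat
    post_ratio_pi <- log_dirichlet(pars1$pi, ah) - log_dirichlet(pars2$pi, ah)
    joint_ratio_pi <-
      complete_log_joint(z, labels, pars1$mu, pars1$lam, pars1$A, pars1$pi, prior) -
      complete_log_joint(z, labels, pars1$mu, pars1$lam, pars1$A, pars2$pi, prior)
    expect_equal(post_ratio_pi, joint_ratio_pi, tolerance = 1e-9)
  }
})

test_that("initialization is reproducible and warm-started", {
  prior <- blink_prior()
  set.seed(6)
  z <- rnorm(500)
  set.seed(7); p1 <- init_params(prior, z)
  set.seed(7); p2 <- init_params(prior, z)
  expect_identical(p1, p2)
  expect_equal(colSums(p1$A), c(1, 1))
  expect_equal(sum(p1$pi), 1)
  expect_true(p1$mu[1] > p1$mu[2]) # ON anchored above OFF
  # warm-start Dirichlet mean keeps the chain sticky: E[A_kk] = 20N/(20N+1)
  diags <- replicate(200, { q <- init_params(prior, z); diag(q$A) })
  expect_gt(mean(diags), 0.999)
})
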