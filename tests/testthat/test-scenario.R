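test_that("scenario validation enforces the physical constraints", {
  expect_error(blink_scenario(tau_on = 1e-4, delta = 5e-4), "exceed the bin width")
  expect_error(blink_scenario(mu_on = 1, mu_off = 2), "mu_on > mu_off")
  expect_error(blink_scenario(mu_on = 5, mu_off = -1), "mu_on > mu_off")
  sc <- default_scenario()
  expect_s3_class(sc, "blink_scenario")
  expect_equal(sc$tau_on, 0.0176)
  expect_equal(sc$tau_off, 0.0078)
  expect_equal(sc$delta, 5e-4)
  expect_equal(sc$mu_on, 20)
  expect_identical(sc$noise_model, "poisson")
  # invariants hold for the default parameter set
  expect_true(sc$tau_on > sc$delta && sc$tau_off > sc$delta)
  expect_true(sc$mu_on > sc$mu_off && sc$mu_off >= 0)
  expect_true(sc$duration >= 10 * max(sc$tau_on, sc$tau_off))
})

test_that("scenario transition matrix encodes geometric dwells and stationary occupancy", {
  m <- scenario_transition_matrix(default_scenario())
  expect_equal(colSums(m$A), c(on = 1, off = 1))
  expect_equal(unname(m$A["on", "on"]), 1 - 5e-4 / 0.0176)
  expect_equal(unname(m$pi["on"]), 0.0176 / (0.0176 + 0.0078))
  # inverting the discretization recovers the dwell constants exactly
  tau <- relaxation_from_transition(m$A, 5e-4)
  expect_equal(unname(tau), c(0.0176, 0.0078))
})

test_that("simulate_state_chain follows the Markov law", {
  # absorbing chain: identity transitions never leave the initial state
  s <- simulate_state_chain(diag(2), c(1, 0), 50, seed = 1)
  expect_identical(s, rep(1L, 50))
  # determinism under a fixed seed
  A <- matrix(c(0.97, 0.03, 0.06, 0.94), 2)
  s1 <- simulate_state_chain(A, c(0.5, 0.5), 1000, seed = 7)
  s2 <- simulate_state_chain(A, c(0.5, 0.5), 1000, seed = 7)
  expect_identical(s1, s2)
  # geometric dwell-length law: mean ON dwell = 1 / (1 - A_kk) bins
  s <- simulate_state_chain(A, c(0.5, 0.5), 4e5, seed = 11)
  r <- rle(s)
  on_runs <- r$lengths[r$values == 1L]
  expect_equal(mean(on_runs), 1 / (1 - 0.97), tolerance = 0.05)
  # long-run occupancy matches the stationary distribution tau_on/(tau_on+tau_off)
  m <- scenario_transition_matrix(default_scenario())
  s <- simulate_state_chain(m$A, m$pi, 1e5, seed = 12)
  expect_equal(mean(s == 1L), unname(m$pi["on"]), tolerance = 0.03)
  # validation errors name the offending column
  Abad <- matrix(c(0.9, 0.2, 0.06, 0.94), 2)
  expect_error(simulate_state_chain(Abad, c(0.5, 0.5), 10), "column\\(s\\): 1")
  expect_error(simulate_state_chain(A, c(0.7, 0.5), 10), "pi must be")
})

test_that("simulate_trace reproduces the requested count statistics", {
  sc <- blink_scenario(mu_on = 20, mu_off = 0, duration = 50, seed = 1)
  states <- rep(1L, 1e5)
  tr <- simulate_trace(states, sc, seed = 2)
  expect_true(all(tr$counts >= 0))
  # Poisson moments at mu = 20 over 1e5 bins
  expect_equal(mean(tr$counts), 20, tolerance = 0.14 / 20)
  expect_equal(var(tr$counts) / mean(tr$counts), 1, tolerance = 0.02)
  # mu_off = 0 with Poisson noise emits exactly zero in OFF bins
  states2 <- rep(c(1L, 2L), 500)
  tr2 <- simulate_trace(states2, sc, seed = 3)
  expect_true(all(tr2$counts[states2 == 2L] == 0))
  # degenerate Gaussian emission: sd -> 0 gives round(mu) everywhere
  scg <- blink_scenario(mu_on = 19.7, mu_off = 1.2, noise_model = "gaussian",
                        gaussian_sd_on = 0, gaussian_sd_off = 0,
                        duration = 1, seed = 1)
  trg <- simulate_trace(states2, scg, seed = 4)
  expect_true(all(trg$counts[states2 == 1L] == 20))
  expect_true(all(trg$counts[states2 == 2L] == 1))
})

test_that("simulate_arrivals is a rate-switching Poisson process", {
  # effectively single-state record: enormous ON dwell, so the photon count
  # follows the plain Poisson count law N ~ Pois(r * T)
  sc <- blink_scenario(tau_on = 1e6, tau_off = 0.01, mu_on = 20, mu_off = 1,
                       delta = 5e-4, duration = 5, seed = 3)
  arr <- simulate_arrivals(sc, seed = 3)
  r <- sc$mu_on / sc$delta
  expect_lt(abs(length(arr$times) - r * sc$duration), 3 * sqrt(r * sc$duration))
  expect_true(all(diff(arr$times) > 0))
  expect_true(all(arr$times >= 0 & arr$times < sc$duration))
  # quantized to the detector tick
  ticks <- arr$times / arr$resolution
  expect_true(all(abs(ticks - round(ticks)) < 1e-6))
  # binning the arrivals reproduces the scenario's per-bin count statistics
  sc2 <- default_scenario(duration = 20, seed = 5)
  arr2 <- simulate_arrivals(sc2)
  tr <- rebin(arr2, sc2$delta)
  occ <- sc2$tau_on / (sc2$tau_on + sc2$tau_off)
  expected_mean <- occ * sc2$mu_on + (1 - occ) * sc2$mu_off
  expect_equal(mean(tr$counts), expected_mean, tolerance = 0.05)
  # OFF periods at zero rate contain no photons: with mu_off = 0 every
  # photon-free stretch longer than a few ms is consistent with an OFF dwell
  sc3 <- blink_scenario(mu_off = 0, duration = 10, seed = 6)
  arr3 <- simulate_arrivals(sc3)
  tr3 <- rebin(arr3, sc3$delta)
  expect_gt(mean(tr3$counts == 0), 0.15) # OFF occupancy ~ 0.31, minus overlap
})

test_that("generators are reproducible and seeds decouple", {
  sim1 <- simulate_blinking(default_scenario(duration = 1, seed = 9))
  sim2 <- simulate_blinking(default_scenario(duration = 1, seed = 9))
  sim3 <- simulate_blinking(default_scenario(duration = 1, seed = 10))
  expect_identical(sim1$trace$counts, sim2$trace$counts)
  expect_identical(sim1$states, sim2$states)
  expect_false(identical(sim1$trace$counts, sim3$trace$counts))
})
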