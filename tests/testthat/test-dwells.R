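test_that("dwell extraction is an exact run-length decomposition", {
  d <- extract_dwells(c(1, 1, 2, 1, 1, 1), delta = 5e-4)
  expect_equal(d$on$durations, c(1.0e-3, 1.5e-3))
  expect_equal(d$off$durations, 0.5e-3)
  expect_equal(d$on$n_events, 2)
  # censoring drops the boundary runs
  dc <- extract_dwells(c(1, 1, 2, 1, 1, 1), delta = 5e-4, boundary = "censor")
  expect_equal(dc$on$n_events, 0)
  expect_equal(dc$off$durations, 0.5e-3)
  # an all-ON sequence has no complete dwell under censoring
  expect_equal(extract_dwells(rep(1L, 10), delta = 1e-3,
                              boundary = "censor")$on$n_events, 0)
  # a marginal of exactly 0.5 resolves to OFF
  dm <- extract_dwells(c(0.9, 0.5, 0.9), delta = 1e-3)
  expect_equal(dm$off$durations, 1e-3)
  expect_equal(dm$on$n_events, 2)
})

test_that("dwell-time density follows the half-open histogram rule and normalizes", {
  d <- dwell_set(c(1, 1, 2, 3) * 1e-3, "on", delta = 1e-3)
  pdf <- dwell_pdf(d, dtau = 1e-3)
  expect_equal(pdf$counts, c(0, 2, 1, 1))
  expect_equal(pdf$density, c(0, 0.5, 0.25, 0.25) / 1e-3)
  expect_equal(sum(pdf$density) * pdf$dtau, 1, tolerance = 1e-12)
  # all events in one cell: density 1/dtau there
  d1 <- dwell_set(rep(2.5e-3, 7), "off", delta = 5e-4)
  p1 <- dwell_pdf(d1, dtau = 2e-3)
  expect_equal(p1$density, c(0, 1 / 2e-3))
  expect_equal(sum(p1$counts), 7)
  expect_error(dwell_pdf(dwell_set(numeric(0), "on", delta = 1e-3)), "empty")
})

test_that("exponential dwell fits recover the decay constant", {
  d <- dwell_set(c(2, 4, 6) * 1e-3, "on", delta = 1e-3)
  f <- suppressWarnings(fit_exponential(d, "mle"))
  expect_equal(f$s, 4e-3)
  expect_equal(f$stderr, 4e-3 / sqrt(3))
  # sampling distribution of the MLE at the reference event count
  set.seed(8)
  s_true <- 17.56e-3
  draws <- pmax(1, round(rexp(2557, 1 / s_true) / 1e-3)) * 1e-3
  dd <- dwell_set(draws, "on", delta = 1e-3)
  fm <- fit_exponential(dd, "mle")
  expect_lt(abs(fm$s - s_true), 3 * s_true / sqrt(2557) + 1e-3 / 2)
  # least-squares on exact (noise-free) discretized exponential densities
  s0 <- 10e-3; dtau <- 2e-3 # dtau = s/5
  grid <- seq_len(60)
  probs <- exp(-(grid - 1) * dtau / s0) - exp(-grid * dtau / s0)
  counts <- round(1e6 * probs)
  durations <- rep((grid - 0.5) * dtau, counts) # midpoints, multiples of 1 ms
  dl <- dwell_set(durations, "on", delta = 1e-3)
  fl <- fit_exponential(dl, "histogram_lsq", dtau = dtau)
  expect_equal(fl$s, s0, tolerance = 0.01)
  expect_error(fit_exponential(dwell_set(numeric(0), "on", delta = 1e-3)),
               "empty")
})

test_that("transition-matrix relaxation times invert the geometric dwell law", {
  A <- matrix(c(0.9, 0.1, 0.05, 0.95), 2)
  tau <- relaxation_from_transition(A, 5e-4)
  expect_equal(unname(tau["on"]), 5e-3)
  expect_equal(unname(tau["off"]), 1e-2)
  # A_kk = 0: the minimum resolvable dwell is one bin
  expect_equal(unname(relaxation_from_transition(matrix(c(0, 1, 1, 0), 2),
                                                 5e-4)["on"]), 5e-4)
  # A_kk = 1 is a flagged sentinel, not a crash
  expect_warning(tau1 <- relaxation_from_transition(diag(2), 5e-4), "infinite")
  expect_true(all(is.infinite(tau1)))
  # Monte-Carlo consistency with simulated geometric dwells
  A2 <- matrix(c(0.95, 0.05, 0.05, 0.95), 2)
  s <- simulate_state_chain(A2, c(0.5, 0.5), 1e5, seed = 13)
  d <- extract_dwells(s, delta = 5e-4, boundary = "censor")
  expect_equal(mean(d$on$durations), unname(
    relaxation_from_transition(A2, 5e-4)["on"]), tolerance = 0.03)
})

test_that("pooling concatenates dwell sets and preserves fit algebra", {
  d1 <- dwell_set(c(1, 2, 3) * 1e-3, "on", delta = 1e-3)
  d2 <- dwell_set(c(4, 5, 6, 7) * 1e-3, "on", delta = 1e-3)
  pooled <- pool_dwells(list(d1, d2))
  expect_equal(pooled$n_events, 7)
  expect_equal(sort(pooled$durations), sort(c(d1$durations, d2$durations)))
  # pooled MLE equals the event-count-weighted mean of per-set means
  f <- suppressWarnings(fit_exponential(pooled, "mle"))
  expect_equal(f$s, (3 * mean(d1$durations) + 4 * mean(d2$durations)) / 7)
  expect_error(pool_dwells(list(d1, dwell_set(1e-3, "off", delta = 1e-3))),
               "mixed state")
})

test_that("dwell constants are recovered end to end on a long reference trace", {
  fx <- fixture_fit_long()
  d <- extract_dwells(fx$fit)
  s_on <- fit_exponential(d$on, "mle")$s
  s_off <- fit_exponential(d$off, "mle")$s
  expect_equal(s_on, 0.0176, tolerance = 0.15)
  expect_equal(s_off, 0.0078, tolerance = 0.15)
  # transition-matrix estimates agree with the dwell fits (the two routes to
  # the same relaxation time)
  tau <- relaxation_from_transition(fx$fit$posterior$A, 5e-4)
  expect_equal(unname(tau["on"]), s_on, tolerance = 0.15)
  expect_equal(unname(tau["off"]), s_off, tolerance = 0.15)
})

test_that("recovered dwell census matches the generating chain from 3 bins up", {
  fx <- fixture_fit_long()
  d <- extract_dwells(fx$fit)
  d_true <- extract_dwells(fx$sim$states, delta = 5e-4)
  for (state in c("on", "off")) {
    k_rec <- round(d[[state]]$durations / 5e-4)
    k_tru <- round(d_true[[state]]$durations / 5e-4)
    expect_equal(sum(k_rec >= 3), sum(k_tru >= 3), tolerance = 0.10)
    expect_equal(mean(k_rec[k_rec >= 3]), mean(k_tru[k_tru >= 3]),
                 tolerance = 0.10)
  }
})

test_that("sub-3-bin dwells are under-detected on continuous-time data", {
  # dwells that straddle bin edges (a feature of real, unsynchronized
  # blinking that the bin-level chain generator cannot produce) wash out
  # events shorter than ~3 bins; durations >= 3 bins remain unbiased
  sc <- default_scenario(duration = 20, seed = 55)
  tr <- rebin(simulate_arrivals(sc), sc$delta)
  fit <- blink_hmm(tr, n_iter = 1000, burn_in = 100, seed = 56)
  d <- extract_dwells(fit)
  truth <- c(on = sc$tau_on, off = sc$tau_off)
  for (state in c("on", "off")) {
    tau <- d[[state]]$durations
    delta <- sc$delta
    big <- tau[tau >= 3 * delta]
    # restricted fit (memoryless excess over the 3-bin floor)
    s_hat <- mean(big - 3 * delta)
    expect_equal(s_hat, unname(truth[state]), tolerance = 0.15)
    # were the exponential law complete down to one bin, it would predict
    # many more single-bin events than are actually recovered
    predicted_k1 <- length(big) / exp(-3 * delta / s_hat) *
      (1 - exp(-delta / s_hat))
    expect_lt(sum(round(tau / delta) == 1), 0.8 * predicted_k1)
  }
})
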