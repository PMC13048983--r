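# Lazily built, cached fixtures shared across test files. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Reference-condition fit: 5 s trace at the default scenario, full sampler
# settings (1000 sweeps, burn-in 100).
fixture_fit <- function() {
  fixture("fit_default", function() {
    sim <- simulate_blinking(default_scenario(seed = 41), molecule_id = "fix5s")
    list(sim = sim,
         fit = blink_hmm(sim$trace, n_iter = 1000, burn_in = 100, seed = 42))
  })
}

# Long-trace fit (20 s) for dwell-statistics tests where per-trace event
# counts need to be in the thousands.
fixture_fit_long <- function() {
  fixture("fit_long", function() {
    sc <- default_scenario(duration = 20, seed = 51)
    sim <- simulate_blinking(sc, molecule_id = "fix20s")
    list(scenario = sc, sim = sim,
         fit = blink_hmm(sim$trace, n_iter = 1000, burn_in = 100, seed = 52))
  })
}
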