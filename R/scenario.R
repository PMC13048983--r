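#' Define a synthetic blinking scenario
#'
#' A scenario bundles the physical parameters of a simulated two-state
#' (ON/OFF) blinking fluorophore: exponential mean dwell times, per-bin mean
#' photon counts, the count-noise model, the time-bin width and the trace
#' length. Scenarios drive [simulate_state_chain()], [simulate_trace()] and
#' [simulate_arrivals()].
#'
#' @param tau_on,tau_off Mean ON / OFF dwell times in seconds. Must exceed
#'   `delta`: dwells shorter than one bin cannot be represented.
#' @param mu_on,mu_off Mean photon counts per bin in the ON / OFF state.
#'   `mu_on > mu_off >= 0` is required. The default OFF level of 1 count/bin
#'   represents a nonzero background (detector dark counts, substrate
#'   emission) so that neither emission component is ever degenerate.
#' @param noise_model `"poisson"` (shot-noise counts, the physical default) or
#'   `"gaussian"` (rounded, zero-clipped Gaussian counts matching the
#'   inference model's emission assumption).
#' @param gaussian_sd_on,gaussian_sd_off Count standard deviations used only
#'   when `noise_model = "gaussian"`; default to `sqrt(mu)` (Poisson-matched).
#' @param delta Time-bin width in seconds.
#' @param duration Trace length in seconds. At least
#'   `10 * max(tau_on, tau_off)` is recommended for stable dwell statistics.
#' @param seed Optional integer seed recorded in the scenario and used by the
#'   generators for reproducibility.
#'
#' @return An object of class `"blink_scenario"` (a validated list).
#' @seealso [default_scenario()] for the reference parameter set.
#' @export
#' @examples
#' sc <- blink_scenario(tau_on = 0.02, tau_off = 0.01, mu_on = 25, duration = 2)
#' sc
blink_scenario <- function(tau_on = 0.0176, tau_off = 0.0078,
                           mu_on = 20, mu_off = 1,
                           noise_model = c("poisson", "gaussian"),
                           gaussian_sd_on = sqrt(mu_on),
                           gaussian_sd_off = sqrt(max(mu_off, 1e-12)),
                           delta = 5e-4, duration = 5, seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(is.numeric(tau_on), is.numeric(tau_off), is.numeric(delta),
            delta > 0, is.numeric(duration), duration > 0)
  if (tau_on <= delta || tau_off <= delta)
    stop("mean dwell times must exceed the bin width delta (tau_on = ",
         tau_on, ", tau_off = ", tau_off, ", delta = ", delta, ")")
  if (!(mu_on > mu_off) || mu_off < 0)
    stop("need mu_on > mu_off >= 0 (got mu_on = ", mu_on,
         ", mu_off = ", mu_off, ")")
  if (noise_model == "gaussian" && (gaussian_sd_on < 0 || gaussian_sd_off < 0))
    stop("gaussian noise standard deviations must be nonnegative")
  structure(
    list(tau_on = tau_on, tau_off = tau_off, mu_on = mu_on, mu_off = mu_off,
         noise_model = noise_model,
         gaussian_sd_on = gaussian_sd_on, gaussian_sd_off = gaussian_sd_off,
         delta = delta, duration = duration, seed = seed),
    class = "blink_scenario")
}

#' Reference blinking scenario
#'
#' The default study conditions for the DNA-ATTO655 blinking system: mean ON
#' dwell 17.6 ms, mean OFF dwell 7.8 ms, about 20 detected photons per ON bin
#' at a 0.5 ms bin width, Poisson count noise, and a 5 s trace. The OFF-state
#' mean of 1 count/bin is a background placeholder (the experimental OFF
#' baseline is nonzero but its level is not separately characterized).
#'
#' @param ... Overrides passed to [blink_scenario()].
#' @return A `"blink_scenario"` object.
#' @export
#' @examples
#' default_scenario()$tau_on # 0.0176 s
default_scenario <- function(...) {
  blink_scenario(...)
}

#' @export
print.blink_scenario <- function(x, ...) {
  cat("Blinking scenario\n")
  cat(sprintf("  dwells   : tau_on = %.4g ms, tau_off = %.4g ms\n",
              1e3 * x$tau_on, 1e3 * x$tau_off))
  cat(sprintf("  emission : mu_on = %.4g, mu_off = %.4g counts/bin (%s noise)\n",
              x$mu_on, x$mu_off, x$noise_model))
  cat(sprintf("  sampling : delta = %.4g ms, duration = %.4g s (%d bins)\n",
              1e3 * x$delta, x$duration, n_bins(x)))
  invisible(x)
}

n_bins <- function(scenario) as.integer(floor(scenario$duration / scenario$delta))

#' Discrete-time transition matrix and stationary occupancy of a scenario
#'
#' First-order discretization of exponential dwells: the self-transition
#' probability per bin is `A_kk = 1 - delta / tau_k`, so discrete-time dwells
#' are geometric with mean `tau_k / delta` bins, i.e. mean dwell time `tau_k`.
#' Inverting `tau_k = delta / (1 - A_kk)` recovers the dwell constant, which
#' is exactly how relaxation times are read off a fitted transition matrix by
#' [relaxation_from_transition()].
#'
#' @param scenario A [blink_scenario()].
#' @return A list with `A` (2x2, `A[k, l] = P(to k | from l)`, columns sum to
#'   1, state 1 = ON) and `pi` (stationary occupancy
#'   `tau / (tau_on + tau_off)`).
#' @export
scenario_transition_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "blink_scenario"))
  p_leave_on <- scenario$delta / scenario$tau_on
  p_leave_off <- scenario$delta / scenario$tau_off
  A <- matrix(c(1 - p_leave_on, p_leave_on,
                p_leave_off, 1 - p_leave_off), nrow = 2,
              dimnames = list(to = c("on", "off"), from = c("on", "off")))
  pi <- c(on = scenario$tau_on, off = scenario$tau_off) /
    (scenario$tau_on + scenario$tau_off)
  list(A = A, pi = pi)
}

check_stochastic <- function(A, pi, tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  cs <- colSums(A)
  bad <- which(abs(cs - 1) > tol | apply(A < 0, 2, any))
  if (length(bad))
    stop("columns of A must be probability distributions; offending column(s): ",
         paste(bad, collapse = ", "))
  if (abs(sum(pi) - 1) > tol || any(pi < 0))
    stop("pi must be a probability distribution (sums to ",
         format(sum(pi)), ")")
  invisible(TRUE)
}

#' Simulate a hidden Markov state chain
#'
#' Draws a label sequence from a first-order Markov chain: the first state
#' from `Categorical(pi)`, each subsequent state from the column of `A`
#' indexed by the previous state. State 1 is ON, state 2 is OFF.
#'
#' @param A K x K column-stochastic transition matrix,
#'   `A[k, l] = P(to k | from l)`.
#' @param pi Length-K initial distribution.
#' @param n_bins Number of bins to simulate.
#' @param seed Optional integer seed.
#' @return Integer vector of labels in `1..K`.
#' @export
#' @examples
#' m <- scenario_transition_matrix(default_scenario())
#' s <- simulate_state_chain(m$A, m$pi, 1000, seed = 1)
#' table(s)
simulate_state_chain <- function(A, pi, n_bins, seed = NULL) {
  check_stochastic(A, pi)
  stopifnot(n_bins >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(A)
  n_bins <- as.integer(n_bins)
  u <- runif(n_bins)
  s <- integer(n_bins)
  # inverse-CDF draw against the cumulative columns
  cum_pi <- cumsum(pi)
  cum_A <- apply(A, 2, cumsum)
  s[1] <- findInterval(u[1], cum_pi, left.open = TRUE) + 1L
  for (n in seq_len(n_bins)[-1]) {
    s[n] <- findInterval(u[n], cum_A[, s[n - 1]], left.open = TRUE) + 1L
  }
  pmin.int(s, K)
}

#' Simulate a photon-count trace from a state chain
#'
#' Emits one nonnegative integer count per bin. Under `"poisson"` noise the
#' count is `Poisson(mu_state)`; under `"gaussian"` noise it is a Gaussian
#' draw rounded to the nearest integer and clipped at zero, so synthetic
#' traces are always valid count data even though the inference model treats
#' counts as continuous.
#'
#' @param states Integer label vector from [simulate_state_chain()]
#'   (1 = ON, 2 = OFF).
#' @param scenario A [blink_scenario()].
#' @param seed Optional integer seed.
#' @param molecule_id Label stored in the returned trace.
#' @return A [photon_trace()].
#' @export
simulate_trace <- function(states, scenario, seed = NULL, molecule_id = "sim") {
  stopifnot(inherits(scenario, "blink_scenario"),
            all(states %in% c(1L, 2L)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  mu <- c(scenario$mu_on, scenario$mu_off)[states]
  counts <- switch(scenario$noise_model,
    poisson = rpois(n, mu),
    gaussian = {
      sd <- c(scenario$gaussian_sd_on, scenario$gaussian_sd_off)[states]
      pmax(0, round(rnorm(n, mu, sd)))
    })
  photon_trace(counts, delta = scenario$delta, molecule_id = molecule_id)
}

#' Simulate a state chain plus trace in one call
#'
#' Convenience wrapper: builds the scenario's discrete-time transition matrix,
#' simulates the chain from its stationary distribution, and emits counts.
#' Uses `scenario$seed` when set.
#'
#' @param scenario A [blink_scenario()].
#' @param molecule_id Label stored in the trace.
#' @return List with `trace` (a [photon_trace()]) and `states` (the
#'   ground-truth label vector).
#' @export
#' @examples
#' sim <- simulate_blinking(default_scenario(seed = 1))
#' mean(sim$trace$counts[sim$states == 1]) # close to mu_on
simulate_blinking <- function(scenario, molecule_id = "sim") {
  stopifnot(inherits(scenario, "blink_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  m <- scenario_transition_matrix(scenario)
  states <- simulate_state_chain(m$A, m$pi, n_bins(scenario))
  trace <- simulate_trace(states, scenario, molecule_id = molecule_id)
  list(trace = trace, states = states)
}

#' Simulate photon arrival times
#'
#' Rate-switching Poisson process: the molecule alternates between ON and OFF
#' with exponential dwell times `tau_on` / `tau_off`; within a dwell, photons
#' arrive as a homogeneous Poisson process at rate `mu_state / delta`.
#' Arrival times are quantized to the detector tick (`resolution`, default
#' 80 ns, the stated counting-board resolution) and deduplicated so they are
#' strictly increasing.
#'
#' @param scenario A [blink_scenario()].
#' @param resolution Detector tick in seconds; `0` disables quantization.
#' @param seed Optional integer seed.
#' @return An object of class `"photon_arrivals"`: list with `times`
#'   (strictly increasing, seconds), `resolution`, and `duration`.
#' @export
simulate_arrivals <- function(scenario, resolution = 80e-9, seed = NULL) {
  stopifnot(inherits(scenario, "blink_scenario"), resolution >= 0)
  if (is.null(seed)) seed <- scenario$seed
  if (!is.null(seed)) set.seed(seed)
  rate <- c(scenario$mu_on, scenario$mu_off) / scenario$delta
  tau <- c(scenario$tau_on, scenario$tau_off)
  occ <- tau / sum(tau)
  state <- if (runif(1) < occ[1]) 1L else 2L
  t0 <- 0
  times <- vector("list", 64L)
  i <- 0L
  while (t0 < scenario$duration) {
    dwell <- rexp(1, 1 / tau[state])
    t1 <- min(t0 + dwell, scenario$duration)
    n_ph <- if (rate[state] > 0) rpois(1, rate[state] * (t1 - t0)) else 0L
    if (n_ph > 0) {
      i <- i + 1L
      times[[i]] <- sort(runif(n_ph, t0, t1))
    }
    t0 <- t1
    state <- 3L - state
  }
  t <- unlist(times[seq_len(i)], use.names = FALSE)
  if (is.null(t)) t <- numeric(0)
  if (resolution > 0) t <- unique(floor(t / resolution) * resolution)
  t <- t[t < scenario$duration]
  structure(list(times = t, resolution = resolution,
                 duration = scenario$duration),
            class = "photon_arrivals")
}

#' @export
print.photon_arrivals <- function(x, ...) {
  cat(sprintf("Photon arrival record: %d photons over %.4g s (tick %.3g ns)\n",
              length(x$times), x$duration, 1e9 * x$resolution))
  invisible(x)
}
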