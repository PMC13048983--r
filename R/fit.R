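#' Fit the blinking hidden Markov model by blocked Gibbs sampling
#'
#' Infers the hidden ON/OFF sequence and model parameters of a two-state
#' Gaussian-emission HMM from a photon-count trace. Counts are standardized
#' to zero mean and unit variance; each Gibbs sweep draws, in order, the full
#' hidden sequence by forward-filtered backward sampling, the emission
#' (mean, precision) pairs from their Gauss-Gamma conditionals, the
#' initial-state distribution and the transition-matrix columns from their
#' Dirichlet conditionals. The first `prior$warm_sweeps` sweeps use a sticky
#' warm-start transition concentration. Components are kept in canonical
#' order (state 1 = ON = brighter mean) at every sweep so posterior averages
#' are immune to label switching. Emission parameters are reported both on
#' the standardized scale and de-standardized to counts/bin.
#'
#' @param trace A [photon_trace()] (or numeric count vector together with
#'   `delta`).
#' @param prior A [blink_prior()].
#' @param n_iter Total number of Gibbs sweeps.
#' @param burn_in Sweeps discarded before posterior averaging
#'   (`burn_in < n_iter`; must cover the warm-start phase).
#' @param seed Optional integer seed; with a seed two runs are identical.
#' @param delta Bin width in seconds, used only when `trace` is a bare
#'   numeric vector.
#' @return An object of class `"blink_hmm"` with components
#'   \describe{
#'     \item{posterior}{post-burn-in means: `mu`, `sigma2` (counts/bin),
#'       `mu_std`, `lam_std` (standardized scale), `A`, `pi`, `w`
#'       (occupancy), `n_on_mean`, `n_off_mean`.}
#'     \item{chains}{per-sweep draws of the parameters (raw-scale `mu` and
#'       `sigma2`, `A`, `pi`, `n_on`).}
#'     \item{objective}{per-sweep surrogate log-likelihood and its emission /
#'       initial / transition terms plus the stationary approximation.}
#'     \item{state_marginal}{per-bin posterior frequency of ON.}
#'     \item{map_states}{consensus sequence by per-bin majority vote (a tie
#'       at exactly 0.5 resolves to OFF).}
#'   }
#' @seealso [summary.blink_hmm()], [extract_dwells()], [model_histogram()]
#' @export
#' @examples
#' sim <- simulate_blinking(default_scenario(duration = 1, seed = 1))
#' fit <- blink_hmm(sim$trace, n_iter = 200, burn_in = 50, seed = 1)
#' fit
blink_hmm <- function(trace, prior = blink_prior(), n_iter = 1000,
                      burn_in = 100, seed = NULL, delta = NULL) {
  if (!inherits(trace, "photon_trace")) {
    if (is.null(delta))
      stop("supply a photon_trace or a numeric count vector plus delta")
    trace <- photon_trace(trace, delta = delta)
  }
  stopifnot(inherits(prior, "blink_prior"), n_iter >= 1,
            burn_in >= 0, burn_in < n_iter)
  if (burn_in < prior$warm_sweeps)
    warning("burn_in is shorter than the warm-start phase; ",
            "warm-start sweeps will enter the posterior averages")
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  std <- standardize(trace)
  z <- std$z
  N <- length(z)
  K <- prior$K

  params <- init_params(prior, z)
  mu_chain <- matrix(NA_real_, n_iter, K)
  sigma2_chain <- matrix(NA_real_, n_iter, K)
  A_chain <- array(NA_real_, c(n_iter, K, K))
  pi_chain <- matrix(NA_real_, n_iter, K)
  n_on <- integer(n_iter)
  obj <- matrix(NA_real_, n_iter, 5,
                dimnames = list(NULL, c("L", "emission", "initial",
                                        "transition", "approx")))
  marg_on <- numeric(N)
  n_keep <- 0L
  n_flips <- 0L
  A_sum <- matrix(0, K, K)
  pi_sum <- numeric(K)
  mu_std_sum <- numeric(K)
  lam_std_sum <- numeric(K)
  labels <- NULL

  for (i in seq_len(n_iter)) {
    fm <- forward_filter_cpp(z, params$mu, params$lam, params$A, params$pi)
    labels <- backward_sample_cpp(fm$f, params$A,
                                  matrix(runif(N), nrow = 1))[1, ]
    em <- sample_emission_posterior(labels, z, prior)
    params$mu <- em$mu
    params$lam <- em$lam
    # canonical order: state 1 is the brighter (ON) component
    if (K == 2 && params$mu[1] < params$mu[2]) {
      params$mu <- params$mu[2:1]
      params$lam <- params$lam[2:1]
      labels <- 3L - labels
      if (i > burn_in) n_flips <- n_flips + 1L
    }
    params$pi <- sample_initial_posterior(labels[1], prior)$pi
    params$A <- sample_transition_posterior(labels, prior,
                                            warm = i <= prior$warm_sweeps)$A
    sl <- surrogate_loglik(z, labels, params)
    obj[i, ] <- c(sl$L, sl$emission, sl$initial, sl$transition, sl$approx)
    raw <- destandardize_params(params$mu, params$lam, std)
    mu_chain[i, ] <- raw$mu
    sigma2_chain[i, ] <- raw$sigma2
    A_chain[i, , ] <- params$A
    pi_chain[i, ] <- params$pi
    n_on[i] <- sum(labels == 1L)
    if (i > burn_in) {
      n_keep <- n_keep + 1L
      marg_on <- marg_on + (labels == 1L)
      A_sum <- A_sum + params$A
      pi_sum <- pi_sum + params$pi
      mu_std_sum <- mu_std_sum + params$mu
      lam_std_sum <- lam_std_sum + params$lam
    }
  }
  if (n_flips > 0.1 * n_keep)
    warning("label order oscillated in ", n_flips, " of ", n_keep,
            " retained sweeps; the two components may not be identifiable")

  keep <- (burn_in + 1):n_iter
  state_marginal <- marg_on / n_keep
  mu_std <- mu_std_sum / n_keep
  lam_std <- lam_std_sum / n_keep
  raw <- destandardize_params(mu_std, lam_std, std)
  sn <- c("on", "off", if (K > 2) paste0("state", 3:K))[seq_len(K)]
  A_bar <- A_sum / n_keep
  dimnames(A_bar) <- list(to = sn, from = sn)
  posterior <- list(
    mu = setNames(raw$mu, sn),
    sigma2 = setNames(raw$sigma2, sn),
    mu_std = setNames(mu_std, sn),
    lam_std = setNames(lam_std, sn),
    A = A_bar,
    pi = setNames(pi_sum / n_keep, sn),
    w = setNames(c(mean(n_on[keep]) / N, 1 - mean(n_on[keep]) / N), sn[1:2]),
    n_on_mean = mean(n_on[keep]),
    n_off_mean = N - mean(n_on[keep]))

  structure(list(
    posterior = posterior,
    chains = list(mu = mu_chain, sigma2 = sigma2_chain, A = A_chain,
                  pi = pi_chain, n_on = n_on),
    objective = as.data.frame(cbind(sweep = seq_len(n_iter), obj)),
    state_marginal = state_marginal,
    map_states = ifelse(state_marginal > 0.5, 1L, 2L),
    last_states = labels,
    trace = trace,
    std = std[c("center", "scale")],
    prior = prior, n_iter = n_iter, burn_in = burn_in, seed = seed,
    n_label_flips = n_flips, call = cl),
    class = "blink_hmm")
}

#' @export
print.blink_hmm <- function(x, ...) {
  p <- x$posterior
  cat("Blinking HMM fit (", x$n_iter, "Gibbs sweeps, burn-in",
      x$burn_in, ")\n")
  cat(sprintf("  trace     : '%s', %d bins of %.4g ms\n",
              x$trace$molecule_id, length(x$trace$counts),
              1e3 * x$trace$delta))
  cat(sprintf("  emission  : mu_on = %.2f, mu_off = %.2f counts/bin (sigma2 %.2f / %.2f)\n",
              p$mu["on"], p$mu["off"], p$sigma2["on"], p$sigma2["off"]))
  cat(sprintf("  transition: A_on,on = %.4f, A_off,off = %.4f\n",
              p$A["on", "on"], p$A["off", "off"]))
  cat(sprintf("  occupancy : w_on = %.3f, w_off = %.3f\n",
              p$w["on"], p$w["off"]))
  invisible(x)
}

#' @export
coef.blink_hmm <- function(object, ...) {
  p <- object$posterior
  c(mu_on = unname(p$mu["on"]), mu_off = unname(p$mu["off"]),
    sigma2_on = unname(p$sigma2["on"]), sigma2_off = unname(p$sigma2["off"]),
    A_on_on = unname(p$A["on", "on"]), A_off_off = unname(p$A["off", "off"]),
    pi_on = unname(p$pi["on"]), w_on = unname(p$w["on"]))
}

#' @export
fitted.blink_hmm <- function(object, ...) {
  object$posterior$mu[object$map_states]
}

#' @export
residuals.blink_hmm <- function(object, ...) {
  object$trace$counts - unname(fitted(object))
}

#' First sweep at which the monitoring objective has stabilized
#'
#' Smallest sweep index from which on every change of the running mean of the
#' surrogate log-likelihood stays below `tol` (nats/sample).
#'
#' @param x A `"blink_hmm"` fit or a numeric objective trace.
#' @param tol Stability tolerance in nats/sample.
#' @return Integer sweep index (`Inf` if never stable).
#' @export
convergence_sweep <- function(x, tol = 0.01) {
  L <- if (inherits(x, "blink_hmm")) x$objective$L else as.numeric(x)
  r <- cumsum(L) / seq_along(L)
  step <- abs(diff(r))
  bad <- which(step >= tol)
  if (!length(bad)) return(2L)
  if (max(bad) + 2L > length(L)) return(Inf)
  as.integer(max(bad) + 2L)
}

#' Summarize a blinking HMM fit
#'
#' Posterior means and standard deviations of the parameters, relaxation
#' times derived from the averaged transition matrix, occupancy, and the
#' sweep at which the monitoring objective stabilized.
#'
#' @param object A `"blink_hmm"` fit.
#' @param ... Unused.
#' @return Object of class `"summary.blink_hmm"`.
#' @export
summary.blink_hmm <- function(object, ...) {
  keep <- (object$burn_in + 1):object$n_iter
  chains <- object$chains
  psd <- function(m) apply(m[keep, , drop = FALSE], 2, stats::sd)
  A_sd <- apply(chains$A[keep, , , drop = FALSE], c(2, 3), stats::sd)
  tau <- relaxation_from_transition(object$posterior$A, object$trace$delta)
  out <- list(
    posterior = object$posterior,
    sd = list(mu = psd(chains$mu), sigma2 = psd(chains$sigma2),
              A = A_sd, pi = psd(chains$pi)),
    relaxation = tau,
    convergence_sweep = convergence_sweep(object),
    objective_mean = mean(object$objective$L[keep]),
    qc = qc_flag(object),
    n_iter = object$n_iter, burn_in = object$burn_in,
    delta = object$trace$delta, molecule_id = object$trace$molecule_id,
    n_bins = length(object$trace$counts))
  class(out) <- "summary.blink_hmm"
  out
}

#' @export
print.summary.blink_hmm <- function(x, ...) {
  p <- x$posterior
  cat("Blinking HMM posterior summary --", x$molecule_id, "\n")
  cat(sprintf("  %d bins of %.4g ms; %d sweeps (burn-in %d), objective stable from sweep %s\n",
              x$n_bins, 1e3 * x$delta, x$n_iter, x$burn_in,
              format(x$convergence_sweep)))
  fmt <- function(v, s) paste0(sprintf("%.3f", v), " (", sprintf("%.3f", s), ")")
  cat("  emission means (counts/bin): ON", fmt(p$mu["on"], x$sd$mu[1]),
      " OFF", fmt(p$mu["off"], x$sd$mu[2]), "\n")
  cat("  emission variances        : ON", fmt(p$sigma2["on"], x$sd$sigma2[1]),
      " OFF", fmt(p$sigma2["off"], x$sd$sigma2[2]), "\n")
  cat(sprintf("  A_on,on = %.4f (%.4f), A_off,off = %.4f (%.4f)\n",
              p$A["on", "on"], x$sd$A[1, 1], p$A["off", "off"], x$sd$A[2, 2]))
  cat(sprintf("  relaxation times: tau_on = %.2f ms, tau_off = %.2f ms\n",
              1e3 * x$relaxation["on"], 1e3 * x$relaxation["off"]))
  cat(sprintf("  occupancy w_on = %.3f; mean objective %.4f nats/sample\n",
              p$w["on"], x$objective_mean))
  if (x$qc$flagged)
    cat("  QC: FLAGGED (", paste(x$qc$reasons, collapse = "; "), ")\n")
  else cat("  QC: pass\n")
  invisible(x)
}

#' Simulate new traces from a fitted model
#'
#' Draws state chains from the posterior-mean transition matrix and initial
#' distribution, then emits counts from the posterior-mean Gaussian emission
#' model (rounded and clipped at zero to stay valid count data).
#'
#' @param object A `"blink_hmm"` fit.
#' @param nsim Number of traces.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of [photon_trace()] objects of the same length as the
#'   fitted trace.
#' @export
simulate.blink_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$posterior
  N <- length(object$trace$counts)
  lapply(seq_len(nsim), function(j) {
    s <- simulate_state_chain(unname(p$A), unname(p$pi), N)
    mu <- p$mu[s]
    sd <- sqrt(p$sigma2)[s]
    photon_trace(pmax(0, round(rnorm(N, mu, sd))), delta = object$trace$delta,
                 molecule_id = paste0(object$trace$molecule_id, "_sim", j))
  })
}

#' Plot a blinking HMM fit
#'
#' `which = "trace"` draws the photon-count trajectory with the inferred ON
#' marginal overlaid (scaled to the ON mean); `which = "objective"` draws the
#' per-sweep surrogate log-likelihood and its emission and transition terms
#' with the `-1.4189` baseline.
#'
#' @param x A `"blink_hmm"` fit.
#' @param which `"trace"` or `"objective"`.
#' @param max_bins Largest number of bins to draw in the trace panel.
#' @param ... Passed to [plot()].
#' @export
plot.blink_hmm <- function(x, which = c("trace", "objective"),
                           max_bins = 4000, ...) {
  which <- match.arg(which)
  if (which == "trace") {
    n <- min(length(x$trace$counts), max_bins)
    t_ms <- (seq_len(n) - 0.5) * x$trace$delta * 1e3
    plot(t_ms, x$trace$counts[seq_len(n)], type = "l", col = "grey40",
         xlab = "time (ms)", ylab = "counts / bin",
         main = paste("Trace", x$trace$molecule_id), ...)
    lines(t_ms, x$state_marginal[seq_len(n)] * x$posterior$mu["on"],
          col = "forestgreen")
    legend("topright", legend = c("counts", "P(ON) x mu_on"),
           col = c("grey40", "forestgreen"), lty = 1, bty = "n")
  } else {
    o <- x$objective
    rng <- range(o$L, o$emission, o$transition, -1.5, finite = TRUE)
    plot(o$sweep, o$L, type = "l", ylim = rng, xlab = "Gibbs sweep",
         ylab = "nats / sample", main = "Surrogate log-likelihood", ...)
    lines(o$sweep, o$emission, col = "purple")
    lines(o$sweep, o$transition, col = "forestgreen")
    abline(h = -(1 + log(2 * pi)) / 2, lty = 3)
    legend("bottomright", legend = c("total", "emission", "transition",
                                     "baseline"),
           col = c("black", "purple", "forestgreen", "black"),
           lty = c(1, 1, 1, 3), bty = "n")
  }
  invisible(x)
}
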