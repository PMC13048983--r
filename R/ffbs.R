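#' Forward filtering pass
#'
#' Computes the normalized forward weights `f[n, k]` proportional to the
#' joint probability of the observations up to bin `n` and state `k` at bin
#' `n`: `f[1, k] ~ pi_k N(z_1 | mu_k, 1/lam_k)` and
#' `f[n, k] ~ N(z_n | mu_k, 1/lam_k) * sum_l A[k, l] f[n-1, l]`, renormalized
#' at every step with the log normalizer stored so the unnormalized quantity
#' (and the marginal likelihood) is recoverable:
#' `log f_unnorm[n, k] = log f[n, k] + cumsum(log_norm)[n]`.
#'
#' @param z Standardized counts.
#' @param params List with `mu`, `lam`, `A` (column-stochastic,
#'   `A[k, l] = P(to k | from l)`), `pi`.
#' @return Object of class `"forward_messages"`: list with `f` (N x K, rows
#'   sum to 1) and `log_norm` (length N).
#' @export
forward_filter <- function(z, params) {
  stopifnot(is.numeric(z), length(z) >= 1,
            all(c("mu", "lam", "A", "pi") %in% names(params)))
  if (any(params$lam <= 0)) stop("precision lam must be positive")
  check_stochastic(params$A, params$pi)
  out <- forward_filter_cpp(as.numeric(z), as.numeric(params$mu),
                            as.numeric(params$lam), params$A,
                            as.numeric(params$pi))
  structure(list(f = out$f, log_norm = as.numeric(out$log_norm)),
            class = "forward_messages")
}

#' Backward sampling of the hidden state sequence
#'
#' Draws the full state sequence from its exact conditional posterior given
#' the parameters. The last bin is drawn from the final filter row; going
#' backward, bin `n` is drawn from weights
#' `eta[k, n] ~ f[n, k] * A[l, k]` with `l` the already-sampled state at bin
#' `n + 1`. The backward message is never materialized: the sampling
#' conditional depends only on the forward weights and the transition matrix.
#'
#' @param fm A `"forward_messages"` object from [forward_filter()].
#' @param A The transition matrix used in the forward pass.
#' @param n Number of independent sequence draws.
#' @return For `n = 1` an integer label vector; otherwise an `n` x N integer
#'   matrix with one draw per row.
#' @export
backward_sample <- function(fm, A, n = 1) {
  stopifnot(inherits(fm, "forward_messages"), is.matrix(A),
            ncol(fm$f) == nrow(A), n >= 1)
  N <- nrow(fm$f)
  u <- matrix(runif(n * N), nrow = n)
  S <- backward_sample_cpp(fm$f, A, u)
  if (n == 1) S[1, ] else S
}

#' Per-sample surrogate log-likelihood of a state assignment
#'
#' The monitoring objective of the Gibbs sampler, in nats per sample: the
#' complete-data log-likelihood of the current draw divided by the trace
#' length, decomposed into emission, initial-state and transition terms.
#' Also returns the stationary approximation that drops the initial term and
#' replaces the emission quadratic by its expectation,
#' `0.5 * sum_k w_k log(lam_k) + baseline + sum_l w_l sum_k A[k,l] log A[k,l]`,
#' with the constant baseline `-(1 + log(2 pi)) / 2 = -1.4189`. An observed
#' transition with zero probability yields `-Inf` with a warning.
#'
#' @param z Standardized counts.
#' @param labels Integer state labels in `1..K`.
#' @param params List with `mu`, `lam`, `A`, `pi`.
#' @return List with `L`, `emission`, `initial`, `transition` (exact terms),
#'   `approx` (stationary approximation), `baseline`, and `w` (state
#'   occupancy frequencies).
#' @export
surrogate_loglik <- function(z, labels, params) {
  N <- length(z)
  stopifnot(length(labels) == N, N >= 2)
  mu <- params$mu; lam <- params$lam; A <- params$A; pi0 <- params$pi
  K <- length(mu)
  emission <- sum(emission_log_density(z, mu[labels], lam[labels])) / N
  initial <- log(pi0[labels[1]]) / N
  from <- labels[-N]; to <- labels[-1]
  p_tr <- A[cbind(to, from)]
  if (any(p_tr == 0)) {
    warning("observed transition with zero probability under A; transition term is -Inf")
    transition <- -Inf
  } else {
    transition <- sum(log(p_tr)) / N
  }
  w <- tabulate(labels, nbins = K) / N
  baseline <- -(1 + log(2 * pi)) / 2
  AlogA <- A * log(A)
  AlogA[A == 0] <- 0
  approx <- 0.5 * sum(w * log(lam)) + baseline + sum(w * colSums(AlogA))
  list(L = emission + initial + transition,
       emission = emission, initial = initial, transition = transition,
       approx = approx, baseline = baseline, w = w)
}
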