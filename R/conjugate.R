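#' Gaussian emission log-density
#'
#' Log-density of a standardized count under the state-`k` emission model,
#' `0.5 * log(lam / 2 pi) - (lam / 2) * (x - mu)^2`. Vectorized over `x`.
#'
#' @param x Standardized count value(s).
#' @param mu Emission mean.
#' @param lam Emission precision (inverse variance), `> 0`.
#' @return Log-density value(s).
#' @export
#' @examples
#' emission_log_density(0, 0, 1) # -0.5 * log(2 * pi)
emission_log_density <- function(x, mu, lam) {
  if (!is.numeric(lam) || any(lam <= 0))
    stop("precision lam must be positive")
  0.5 * log(lam / (2 * pi)) - 0.5 * lam * (x - mu)^2
}

# Single draw from Dirichlet(conc) via normalized Gamma draws.
rdirichlet1 <- function(conc) {
  g <- rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) <= 0) { # numerically possible only for tiny concentrations
    g <- g + 1e-300
  }
  g / sum(g)
}

#' Draw emission parameters from their conjugate posterior
#'
#' Gauss-Gamma conjugate update given the current state assignment. For each
#' state `k` with occupancy `n_k = sum s_kn`:
#' `nu_hat = n_k + nu`, `m_hat = (sum s_kn I_n + nu m) / nu_hat`,
#' `a_hat = n_k / 2 + a`,
#' `b_hat = (sum s_kn I_n^2 + nu m^2 - nu_hat m_hat^2) / 2 + b`.
#' The precision is drawn `lam_k ~ Gamma(a_hat, rate = b_hat)` and then
#' `mu_k | lam_k ~ Normal(m_hat, 1 / (nu_hat * lam_k))`. A state holding no
#' data recovers the prior exactly.
#'
#' @param labels Integer state labels in `1..K`.
#' @param z Standardized counts, same length as `labels`.
#' @param prior A [blink_prior()].
#' @return List with `mu`, `lam` (length-K draws) and `update` (the posterior
#'   hyperparameters `nu_hat`, `m_hat`, `a_hat`, `b_hat`).
#' @export
sample_emission_posterior <- function(labels, z, prior) {
  stopifnot(length(labels) == length(z), inherits(prior, "blink_prior"))
  K <- prior$K
  n_k <- tabulate(labels, nbins = K)
  sum_x <- vapply(seq_len(K), function(k) sum(z[labels == k]), numeric(1))
  sum_x2 <- vapply(seq_len(K), function(k) sum(z[labels == k]^2), numeric(1))
  nu_hat <- n_k + prior$nu
  m_hat <- (sum_x + prior$nu * prior$m) / nu_hat
  a_hat <- n_k / 2 + prior$a
  b_hat <- 0.5 * (sum_x2 + prior$nu * prior$m^2 - nu_hat * m_hat^2) + prior$b
  if (any(b_hat <= 0))
    stop("degenerate emission posterior (b_hat <= 0) for state(s) ",
         paste(which(b_hat <= 0), collapse = ", "),
         ": a constant-valued state segment collided with the prior")
  lam <- rgamma(K, shape = a_hat, rate = b_hat)
  mu <- rnorm(K, mean = m_hat, sd = 1 / sqrt(nu_hat * lam))
  list(mu = mu, lam = lam,
       update = list(nu_hat = nu_hat, m_hat = m_hat,
                     a_hat = a_hat, b_hat = b_hat))
}

# Transition counts C[k, l] = #{n >= 2 : s_n = k, s_{n-1} = l}.
transition_counts <- function(labels, K) {
  from <- labels[-length(labels)]
  to <- labels[-1]
  matrix(tabulate(to + (from - 1L) * K, nbins = K * K), nrow = K)
}

#' Draw the transition matrix from its conjugate posterior
#'
#' Each column `l` of `A` (the distribution over destination states from
#' state `l`) is drawn from an independent Dirichlet with concentration
#' `beta_hat[, l] = transition counts into each state from l + beta[, l]`.
#' With `warm = TRUE` the warm-start concentration replaces `beta`.
#'
#' @param labels Integer state labels in `1..K` (length at least 2).
#' @param prior A [blink_prior()].
#' @param warm Use the warm-start concentration?
#' @return List with `A` (K x K column-stochastic draw) and `beta_hat`.
#' @export
sample_transition_posterior <- function(labels, prior, warm = FALSE) {
  stopifnot(inherits(prior, "blink_prior"), length(labels) >= 2)
  K <- prior$K
  base <- if (warm) warm_beta(prior, length(labels)) else prior$beta
  beta_hat <- transition_counts(labels, K) + base
  A <- apply(beta_hat, 2, rdirichlet1)
  list(A = A, beta_hat = beta_hat)
}

#' Draw the initial-state distribution from its conjugate posterior
#'
#' `alpha_hat = alpha + one_hot(s_1)`; `pi ~ Dirichlet(alpha_hat)`.
#'
#' @param s1 The state label at the first bin.
#' @param prior A [blink_prior()].
#' @return List with `pi` (length-K draw) and `alpha_hat`.
#' @export
sample_initial_posterior <- function(s1, prior) {
  stopifnot(inherits(prior, "blink_prior"), s1 %in% seq_len(prior$K))
  alpha_hat <- prior$alpha
  alpha_hat[s1] <- alpha_hat[s1] + 1
  list(pi = rdirichlet1(alpha_hat), alpha_hat = alpha_hat)
}

#' Initialize model parameters for the Gibbs sampler
#'
#' Precisions are drawn from the Gamma prior and `pi` from its Dirichlet
#' prior; the transition matrix starts from the sticky warm-start Dirichlet.
#' The emission means are anchored at spread quantiles of the standardized
#' trace (80th for ON, 20th for OFF when K = 2) instead of prior draws: with
#' a symmetric prior (`m = 0` for all states) the components are
#' exchangeable and symmetry breaking can be slow, whereas quantile anchors
#' start the bright component bright.
#'
#' @param prior A [blink_prior()].
#' @param z Standardized counts.
#' @return List with `mu`, `lam`, `A`, `pi`.
#' @export
init_params <- function(prior, z) {
  stopifnot(inherits(prior, "blink_prior"))
  K <- prior$K
  lam <- rgamma(K, shape = prior$a, rate = prior$b)
  probs <- seq(0.8, 0.2, length.out = K)
  mu <- as.numeric(quantile(z, probs = probs, names = FALSE))
  pi <- rdirichlet1(prior$alpha)
  bw <- warm_beta(prior, length(z))
  A <- apply(bw, 2, rdirichlet1)
  list(mu = mu, lam = lam, A = A, pi = pi)
}
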