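# Independent oracles used across test files: exhaustive path enumeration for
# the state posterior and hand-written log-densities for the conjugate checks.
# These never call the sampler code paths they are used to verify.

# All 2^N label sequences (rows) over states {1, 2}.
all_paths <- function(N) {
  g <- do.call(expand.grid, rep(list(1:2), N))
  as.matrix(g[, rev(seq_len(N)), drop = FALSE])
}

# Log joint p(I_{1:N}, S) of one path under fixed parameters (emission chain
# product written out directly).
path_log_joint <- function(path, z, mu, lam, A, pi0) {
  lp <- log(pi0[path[1]]) +
    sum(dnorm(z, mu[path], 1 / sqrt(lam[path]), log = TRUE))
  if (length(path) > 1) {
    from <- path[-length(path)]
    to <- path[-1]
    lp <- lp + sum(log(A[cbind(to, from)]))
  }
  lp
}

# Exact path posterior p(S | I, params) and per-bin marginals by enumeration.
exact_state_posterior <- function(z, mu, lam, A, pi0) {
  paths <- all_paths(length(z))
  lp <- apply(paths, 1, path_log_joint, z = z, mu = mu, lam = lam,
              A = A, pi0 = pi0)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  marg_on <- colSums(p * (paths == 1))
  list(paths = paths, prob = p, log_joint = lp, marg_on = marg_on)
}

# Gauss-Gamma log-density (shape-rate Gamma on the precision).
log_gauss_gamma <- function(mu, lam, m, nu, a, b) {
  dnorm(mu, m, 1 / sqrt(nu * lam), log = TRUE) +
    dgamma(lam, shape = a, rate = b, log = TRUE)
}

log_dirichlet <- function(x, conc) {
  lgamma(sum(conc)) - sum(lgamma(conc)) + sum((conc - 1) * log(x))
}

# Complete-data log joint of Eq.-style factorization: likelihood of counts
# given the path and parameters, the state-chain probability, and the priors.
complete_log_joint <- function(z, labels, mu, lam, A, pi0, prior) {
  K <- prior$K
  lp <- path_log_joint(labels, z, mu, lam, A, pi0)
  lp <- lp + sum(vapply(seq_len(K), function(k)
    log_gauss_gamma(mu[k], lam[k], prior$m, prior$nu, prior$a, prior$b),
    numeric(1)))
  lp <- lp + log_dirichlet(pi0, prior$alpha)
  for (l in seq_len(K)) lp <- lp + log_dirichlet(A[, l], prior$beta[, l])
  lp
}

# Random valid two-state parameters for property tests.
random_params <- function() {
  A <- apply(matrix(rgamma(4, 2, 1), 2), 2, function(c) c / sum(c))
  pi0 <- rgamma(2, 2, 1)
  list(mu = sort(rnorm(2, 0, 2), decreasing = TRUE),
       lam = rgamma(2, 3, 1) + 0.2,
       A = A, pi = pi0 / sum(pi0))
}

# Mean run length (in bins) of a label sequence.
mean_run_length <- function(labels) mean(rle(as.integer(labels))$lengths)
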