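#include <Rcpp.h>
using namespace Rcpp;

// Forward filtering with per-step normalization. The unnormalized forward
// quantity overflows/underflows for long traces, so each step is renormalized
// and the log normalizer stored; the normalized filter is proportional, which
// is all backward sampling needs.
//
// x: standardized counts (length N); mu, lam: emission mean/precision (K);
// A[k,l] = P(to k | from l), columns sum to 1; pi: initial distribution.
// [[Rcpp::export]]
List forward_filter_cpp(NumericVector x, NumericVector mu, NumericVector lam,
                        NumericMatrix A, NumericVector pi) {
  int N = x.size(), K = mu.size();
  NumericMatrix f(N, K);
  NumericVector log_norm(N);
  std::vector<double> le(K), p(K);
  const double l2pi = std::log(2.0 * M_PI);
  for (int n = 0; n < N; ++n) {
    double lemax = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double d = x[n] - mu[k];
      le[k] = 0.5 * (std::log(lam[k]) - l2pi) - 0.5 * lam[k] * d * d;
      if (le[k] > lemax) lemax = le[k];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double prior;
      if (n == 0) {
        prior = pi[k];
      } else {
        prior = 0.0;
        for (int l = 0; l < K; ++l) prior += A(k, l) * f(n - 1, l);
      }
      p[k] = std::exp(le[k] - lemax) * prior;
      tot += p[k];
    }
    if (!(tot > 0.0))
      stop("forward filter underflow at bin %d: all state weights are zero", n + 1);
    for (int k = 0; k < K; ++k) f(n, k) = p[k] / tot;
    log_norm[n] = std::log(tot) + lemax;
  }
  return List::create(_["f"] = f, _["log_norm"] = log_norm);
}

// Backward sampling of hidden labels given normalized forward weights.
// The sampling conditional at bin n is proportional to f[n, k] * A[l, k]
// where l is the already-sampled state at bin n + 1; the last bin is drawn
// from the final filter row. u: n_draws x N uniforms (from R's RNG, so runs
// are reproducible under set.seed). Returns n_draws x N labels in 1..K.
// [[Rcpp::export]]
IntegerMatrix backward_sample_cpp(NumericMatrix f, NumericMatrix A, NumericMatrix u) {
  int N = f.nrow(), K = f.ncol(), M = u.nrow();
  IntegerMatrix S(M, N);
  for (int m = 0; m < M; ++m) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += f(N - 1, k);
    double target = u(m, N - 1) * tot, cum = 0.0;
    int s = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += f(N - 1, k);
      if (target <= cum) { s = k; break; }
    }
    S(m, N - 1) = s + 1;
    for (int n = N - 2; n >= 0; --n) {
      int l = S(m, n + 1) - 1;
      double denom = 0.0;
      for (int k = 0; k < K; ++k) denom += f(n, k) * A(l, k);
      if (!(denom > 0.0))
        stop("backward sampling weight is zero at bin %d: the transition required into the sampled state is forbidden by A", n + 1);
      target = u(m, n) * denom;
      cum = 0.0;
      s = K - 1;
      for (int k = 0; k < K; ++k) {
        cum += f(n, k) * A(l, k);
        if (target <= cum) { s = k; break; }
      }
      S(m, n) = s + 1;
    }
  }
  return S;
}
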