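#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward and Viterbi recursions for a K-state HMM with
// precomputed per-frame log emission densities. Log-domain throughout.

static inline double logsumexp(const std::vector<double> &v) {
  double m = *std::max_element(v.begin(), v.end());
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List forward_backward(NumericMatrix logB, NumericMatrix logPi,
                      NumericVector logpi0) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix xi(K, K);
  std::vector<double> tmp(K);

  for (int k = 0; k < K; ++k) alpha(0, k) = logpi0[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k) tmp[k] = alpha(t - 1, k) + logPi(k, j);
      alpha(t, j) = logsumexp(tmp) + logB(t, j);
    }
  for (int k = 0; k < K; ++k) tmp[k] = alpha(T - 1, k);
  const double loglik = logsumexp(tmp);

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        tmp[j] = logPi(k, j) + logB(t + 1, j) + beta(t + 1, j);
      beta(t, k) = logsumexp(tmp);
    }

  for (int t = 0; t < T; ++t) {
    for (int k = 0; k < K; ++k) tmp[k] = alpha(t, k) + beta(t, k);
    const double norm = logsumexp(tmp);
    for (int k = 0; k < K; ++k) gamma(t, k) = std::exp(tmp[k] - norm);
  }

  // expected transition counts, summed over time
  for (int t = 0; t < T - 1; ++t) {
    double norm = R_NegInf;
    std::vector<double> cell(K * K);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, k) + logPi(k, j) + logB(t + 1, j) +
                   beta(t + 1, j);
        cell[k * K + j] = v;
        if (v > norm) norm = v;
      }
    double s = 0.0;
    for (double v : cell) s += std::exp(v - norm);
    const double lognorm = norm + std::log(s);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j)
        xi(k, j) += std::exp(cell[k * K + j] - lognorm);
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}

// [[Rcpp::export]]
IntegerVector viterbi_path(NumericMatrix logB, NumericMatrix logPi,
                           NumericVector logpi0) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = logpi0[k] + logB(0, k);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int k = 0; k < K; ++k) {
        const double v = delta(t - 1, k) + logPi(k, j);
        if (v > best) { best = v; arg = k; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based states
  return path;
}
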