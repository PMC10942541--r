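#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward for a K-state Gaussian-emission HMM.
// Returns log-likelihood, state posteriors and expected transition counts,
// the sufficient statistics for one EM step.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix trans, NumericVector init) {
  const int n = x.size(), K = mu.size();
  NumericMatrix b(n, K);       // emission densities
  for (int t = 0; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      b(t, k) = std::exp(-0.5 * z * z) / (sigma[k] * 2.5066282746310002);
      if (b(t, k) < 1e-300) b(t, k) = 1e-300;
    }
  NumericMatrix alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector c(n);          // per-step scaling
  double ll = 0.0;
  for (int k = 0; k < K; ++k) alpha(0, k) = init[k] * b(0, k);
  double s0 = 0; for (int k = 0; k < K; ++k) s0 += alpha(0, k);
  c[0] = s0; for (int k = 0; k < K; ++k) alpha(0, k) /= s0;
  for (int t = 1; t < n; ++t) {
    double s = 0;
    for (int k = 0; k < K; ++k) {
      double a = 0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = a * b(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < n; ++t) ll += std::log(c[t]);
  for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double s = 0;
      for (int j = 0; j < K; ++j) s += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / c[t + 1];
    }
  NumericMatrix xi(K, K);      // summed over t
  for (int t = 0; t < n; ++t) {
    double s = 0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); s += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }
  for (int t = 0; t < n - 1; ++t) {
    double s = 0;
    double tmp[16];
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j) {
        tmp[k * K + j] = alpha(t, k) * trans(k, j) * b(t + 1, j) * beta(t + 1, j);
        s += tmp[k * K + j];
      }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j) xi(k, j) += tmp[k * K + j] / s;
  }
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi path (0-based state indices) for the same model.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sigma,
                          NumericMatrix trans, NumericVector init) {
  const int n = x.size(), K = mu.size();
  NumericMatrix logb(n, K);
  for (int t = 0; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double z = (x[t] - mu[k]) / sigma[k];
      logb(t, k) = -0.5 * z * z - std::log(sigma[k]) - 0.9189385332046727;
    }
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k) delta(0, k) = std::log(init[k] + 1e-300) + logb(0, k);
  NumericMatrix ltr(K, K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < K; ++j) ltr(k, j) = std::log(trans(k, j) + 1e-300);
  for (int t = 1; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + ltr(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logb(t, k);
      psi(t, k) = arg;
    }
  IntegerVector path(n);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k) if (delta(n - 1, k) > best) { best = delta(n - 1, k); path[n - 1] = k; }
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}

// Trailing-window percentile (linear interpolation between order statistics,
// R type 7). Window covers the current sample and the w-1 preceding ones;
// early samples use the partial history available.
// [[Rcpp::export]]
NumericVector rolling_trailing_quantile(NumericVector x, int w, double p) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - w + 1);
    buf.assign(x.begin() + lo, x.begin() + i + 1);
    std::sort(buf.begin(), buf.end());
    int m = buf.size();
    double h = (m - 1) * p;
    int f = (int)std::floor(h);
    int cidx = std::min(f + 1, m - 1);
    out[i] = buf[f] + (h - f) * (buf[cidx] - buf[f]);
  }
  return out;
}
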