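// Newton-Raphson fit of the baseline-category multinomial logit with one
// covariate (the hybrid index), used by the genomic-cline machinery.  The
// permutation tests refit this model hundreds of thousands of times, which
// is why it lives in compiled code.
//
// Model: K categories 0..K-1, category 0 baseline,
//   log(P(k)/P(0)) = b0_k + b1_k * h .
// Coefficients are capped at +/- cap on the logit scale so completely
// separated loci stay finite and rank-comparable (flagged).

#include <Rcpp.h>
using namespace Rcpp;

static double loglik(const IntegerVector& y, const NumericVector& h,
                     const NumericMatrix& B, int K) {
  const int n = y.size(), Km1 = K - 1;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double denom = 1.0, lp = 0.0;
    for (int k = 0; k < Km1; ++k) {
      double eta = B(0, k) + B(1, k) * h[i];
      if (eta > 35.0) eta = 35.0; else if (eta < -35.0) eta = -35.0;
      denom += std::exp(eta);
      if (y[i] == k + 1) lp = eta;
    }
    ll += lp - std::log(denom);
  }
  return ll;
}

// solve the (2*Km1) x (2*Km1) system H x = g in place (Gaussian elimination
// with partial pivoting); returns false if singular
static bool solve_sys(std::vector<double>& H, std::vector<double>& g, int d) {
  for (int c = 0; c < d; ++c) {
    int piv = c;
    double best = std::fabs(H[c * d + c]);
    for (int r = c + 1; r < d; ++r) {
      double v = std::fabs(H[r * d + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != c) {
      for (int j = 0; j < d; ++j) std::swap(H[c * d + j], H[piv * d + j]);
      std::swap(g[c], g[piv]);
    }
    for (int r = c + 1; r < d; ++r) {
      double f = H[r * d + c] / H[c * d + c];
      for (int j = c; j < d; ++j) H[r * d + j] -= f * H[c * d + j];
      g[r] -= f * g[c];
    }
  }
  for (int r = d - 1; r >= 0; --r) {
    double s = g[r];
    for (int j = r + 1; j < d; ++j) s -= H[r * d + j] * g[j];
    g[r] = s / H[r * d + r];
  }
  return true;
}

// [[Rcpp::export(name = ".mlogit_fit_cpp")]]
List mlogit_fit_cpp(IntegerVector y, NumericVector h, int K,
                    double cap = 25.0) {
  const int n = y.size(), Km1 = K - 1, d = 2 * Km1;
  NumericMatrix B(2, Km1);
  // start: smoothed log category odds, zero slope
  std::vector<double> cnt(K, 0.5);
  for (int i = 0; i < n; ++i) cnt[y[i]] += 1.0;
  for (int k = 0; k < Km1; ++k) B(0, k) = std::log(cnt[k + 1] / cnt[0]);

  double ll = loglik(y, h, B, K);
  bool separated = false;
  NumericMatrix P(n, Km1);

  for (int iter = 0; iter < 50; ++iter) {
    // probabilities at current B
    for (int i = 0; i < n; ++i) {
      double denom = 1.0;
      for (int k = 0; k < Km1; ++k) {
        double eta = B(0, k) + B(1, k) * h[i];
        if (eta > 35.0) eta = 35.0; else if (eta < -35.0) eta = -35.0;
        P(i, k) = std::exp(eta);
        denom += P(i, k);
      }
      for (int k = 0; k < Km1; ++k) P(i, k) /= denom;
    }
    // gradient (stacked by class: [b0_1, b1_1, b0_2, b1_2, ...])
    std::vector<double> g(d, 0.0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < Km1; ++k) {
        double r = ((y[i] == k + 1) ? 1.0 : 0.0) - P(i, k);
        g[2 * k] += r;
        g[2 * k + 1] += r * h[i];
      }
    // negative Hessian is positive definite; build H = -Hessian
    std::vector<double> H(d * d, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < Km1; ++k)
        for (int l = 0; l <= k; ++l) {
          double w = (k == l) ? P(i, k) * (1.0 - P(i, k))
                              : -P(i, k) * P(i, l);
          double x00 = w, x01 = w * h[i], x11 = w * h[i] * h[i];
          H[(2 * k) * d + (2 * l)] += x00;
          H[(2 * k) * d + (2 * l + 1)] += x01;
          H[(2 * k + 1) * d + (2 * l)] += x01;
          H[(2 * k + 1) * d + (2 * l + 1)] += x11;
        }
    }
    for (int r = 0; r < d; ++r)    // symmetrize upper triangle
      for (int c = r + 1; c < d; ++c) H[r * d + c] = H[c * d + r];

    std::vector<double> step(g);
    std::vector<double> Hc(H);
    if (!solve_sys(Hc, step, d)) {           // ridge fallback
      Hc = H;
      for (int r = 0; r < d; ++r) Hc[r * d + r] += 1e-8;
      if (!solve_sys(Hc, step, d)) break;
    }
    // ascent with step halving, coefficients clamped at +/- cap
    double fac = 1.0, lln = ll;
    NumericMatrix Bn(2, Km1);
    bool moved = false;
    for (int half = 0; half < 20; ++half) {
      for (int k = 0; k < Km1; ++k) {
        Bn(0, k) = B(0, k) + fac * step[2 * k];
        Bn(1, k) = B(1, k) + fac * step[2 * k + 1];
        if (Bn(0, k) > cap) Bn(0, k) = cap; else if (Bn(0, k) < -cap) Bn(0, k) = -cap;
        if (Bn(1, k) > cap) Bn(1, k) = cap; else if (Bn(1, k) < -cap) Bn(1, k) = -cap;
      }
      lln = loglik(y, h, Bn, K);
      if (lln >= ll - 1e-12) { moved = true; break; }
      fac *= 0.5;
    }
    if (!moved) break;
    double delta = lln - ll;
    B = clone(Bn);
    ll = lln;
    for (int k = 0; k < Km1; ++k)
      if (std::fabs(B(0, k)) >= cap || std::fabs(B(1, k)) >= cap)
        separated = true;
    if (delta < 1e-10) break;
  }
  return List::create(_["coefficients"] = B, _["logLik"] = ll,
                      _["separated"] = separated);
}

// fit statistic 2*(logL_fitted - logL_intercept_only); fast path for the
// permutation loop
// [[Rcpp::export(name = ".cline_stat_cpp")]]
double cline_stat_cpp(IntegerVector y, NumericVector h, int K,
                      double cap = 25.0) {
  List fit = mlogit_fit_cpp(y, h, K, cap);
  double ll = as<double>(fit["logLik"]);
  const int n = y.size();
  std::vector<double> cnt(K, 0.0);
  for (int i = 0; i < n; ++i) cnt[y[i]] += 1.0;
  double ll0 = 0.0;
  for (int k = 0; k < K; ++k)
    if (cnt[k] > 0) ll0 += cnt[k] * std::log(cnt[k] / n);
  return 2.0 * (ll - ll0);
}
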