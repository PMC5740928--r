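// Dual coordinate descent for the L2-regularized L1-loss linear SVM
// (Hsieh et al. 2008 style), dense features, optional bias via an
// augmented constant feature appended by the caller. Samples are stored
// as COLUMNS of Xt so each coordinate step touches contiguous memory.
// Deterministic: permutations come from an internal xorshift RNG seeded
// explicitly.

#include <Rcpp.h>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13; s ^= s >> 7; s ^= s << 17;
  return s;
}

// [[Rcpp::export]]
List dcd_svm(NumericMatrix Xt, NumericVector y, double C,
             double tol, int max_epochs, double seed) {
  const int d = Xt.nrow(), n = Xt.ncol();
  const double *xp = REAL(Xt);
  std::vector<double> w(d, 0.0), alpha(n, 0.0), qd(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = xp + (size_t)i * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qd[i] = s;
  }
  uint64_t state = (uint64_t)seed * 2654435761u + 88172645463325252ull;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int epoch = 0;
  double max_viol = 0.0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(xorshift64(state) % (uint64_t)(i + 1));
      std::swap(idx[i], idx[j]);
    }
    max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = idx[k];
      if (qd[i] <= 0) continue;
      const double *xi = xp + (size_t)i * d;
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * xi[j];
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] <= 0.0) pg = std::min(g, 0.0);
      else if (alpha[i] >= C) pg = std::max(g, 0.0);
      if (std::fabs(pg) > max_viol) max_viol = std::fabs(pg);
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qd[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0)
          for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
      }
    }
    if (max_viol < tol) { ++epoch; break; }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["epochs"] = epoch,
                      _["max_violation"] = max_viol);
}

// decision values t(Xt) %*% w without materializing crossproducts in R
// [[Rcpp::export]]
NumericVector dense_decision(NumericMatrix Xt, NumericVector w) {
  const int d = Xt.nrow(), n = Xt.ncol();
  const double *xp = REAL(Xt);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = xp + (size_t)i * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * w[j];
    out[i] = s;
  }
  return out;
}
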