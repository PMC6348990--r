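#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Trimmed mean of a buffer: drop k = floor(n*(1-conf)/2) values from each
// tail, average the rest. Mirrors the R-side arithmetic exactly.
static inline void trimmed_mean(std::vector<double>& buf, double conf,
                                double& mean_out, int& n_out) {
  const int n = (int)buf.size();
  if (n == 0) { mean_out = NA_REAL; n_out = 0; return; }
  const int k = (int)std::floor(n * (1.0 - conf) / 2.0);
  if (n - 2 * k < 1) { mean_out = NA_REAL; n_out = 0; return; }
  if (k == 0) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += buf[i];
    mean_out = s / n;
    n_out = n;
    return;
  }
  // only the k extreme values on each side matter: select instead of sort
  std::nth_element(buf.begin(), buf.begin() + k, buf.end());
  std::nth_element(buf.begin() + k, buf.end() - k - 1, buf.end());
  double s = 0.0;
  for (int i = k; i < n - k; ++i) s += buf[i];
  mean_out = s / (n - 2 * k);
  n_out = n - 2 * k;
}

// [[Rcpp::export]]
List cpp_trimmed_col_stats(NumericMatrix x, double conf) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericVector mean(nc);
  IntegerVector n(nc);
  std::vector<double> buf;
  buf.reserve(nr);
  for (int j = 0; j < nc; ++j) {
    buf.clear();
    for (int i = 0; i < nr; ++i) {
      const double v = x(i, j);
      if (!NumericVector::is_na(v)) buf.push_back(v);
    }
    double m; int cnt;
    trimmed_mean(buf, conf, m, cnt);
    mean[j] = m;
    n[j] = cnt;
  }
  return List::create(_["mean"] = mean, _["n"] = n);
}

// Quantile type 7 (R default) of a sorted vector.
static inline double quantile7(const std::vector<double>& v, double p) {
  const int m = (int)v.size();
  if (m == 0) return NA_REAL;
  if (m == 1) return v[0];
  const double h = (m - 1) * p;
  const int lo = (int)std::floor(h);
  const int hi = lo + 1 < m ? lo + 1 : lo;
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

// draws: n_perm x n_test matrix of 1-based row indices into x.
// For each permutation, trimmed per-column means of the sampled rows are
// computed; bounds are the per-column type-7 quantiles of those means.
// [[Rcpp::export]]
List cpp_permutation_bounds(NumericMatrix x, IntegerMatrix draws, double conf,
                            double lo_p, double hi_p) {
  const int nc = x.ncol();
  const int n_perm = draws.nrow(), n_test = draws.ncol();
  NumericMatrix perm_means(n_perm, nc);
  std::vector<double> buf;
  buf.reserve(n_test);
  std::vector<int> idx(n_test);
  const double* xp = REAL(x);
  const int nr = x.nrow();
  for (int b = 0; b < n_perm; ++b) {
    for (int t = 0; t < n_test; ++t) idx[t] = draws(b, t) - 1;
    for (int j = 0; j < nc; ++j) {
      const double* col = xp + (R_xlen_t)j * nr;
      buf.clear();
      for (int t = 0; t < n_test; ++t) {
        const double v = col[idx[t]];
        if (!ISNAN(v)) buf.push_back(v);
      }
      double m; int cnt;
      trimmed_mean(buf, conf, m, cnt);
      perm_means(b, j) = m;
    }
  }
  NumericVector lower(nc), upper(nc);
  std::vector<double> col;
  col.reserve(n_perm);
  for (int j = 0; j < nc; ++j) {
    col.clear();
    for (int b = 0; b < n_perm; ++b) {
      const double v = perm_means(b, j);
      if (!NumericVector::is_na(v)) col.push_back(v);
    }
    std::sort(col.begin(), col.end());
    lower[j] = quantile7(col, lo_p);
    upper[j] = quantile7(col, hi_p);
  }
  return List::create(_["lower"] = lower, _["upper"] = upper);
}
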