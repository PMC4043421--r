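#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shape codes shared with R: 1 gaussian, 2 square, 3 triangle.

// Discrete normalizer: total unnormalized weight over integer offsets -r..r.
// Summed in a fixed order so that every caller sees the identical double.
// [[Rcpp::export]]
double kernel_total_cpp(int shape, double h, int r) {
  if (shape == 2) return 2.0 * r + 1.0;
  double s = 0.0;
  if (shape == 1) {
    for (int j = 1; j <= r; ++j) {
      double dj = j;
      s += exp(-(dj * dj) / (2.0 * h * h));
    }
  } else {
    for (int j = 1; j <= r; ++j) {
      double dj = j;
      s += 1.0 - dj / (6.0 * h);
    }
  }
  return 1.0 + 2.0 * s;
}

// Sum of per-point kernels evaluated at sorted queries. x is sorted; each
// point i contributes raw(q - x_i) / total_i / n to every query within its
// support radius r_i. Kernels are added in ascending i, matching the dense
// accumulator's order, so results agree bitwise with a dense-track lookup.
// [[Rcpp::export]]
NumericVector kde_eval_sorted_cpp(NumericVector x, NumericVector h, int shape,
                                  NumericVector total, IntegerVector r,
                                  NumericVector qs) {
  int n = x.size(), m = qs.size();
  NumericVector f(m);
  double dn = n;
  for (int i = 0; i < n; ++i) {
    double lo = x[i] - r[i], hi = x[i] + r[i];
    int a = std::lower_bound(qs.begin(), qs.end(), lo) - qs.begin();
    int b = std::upper_bound(qs.begin(), qs.end(), hi) - qs.begin();
    if (shape == 1) {
      double hh = 2.0 * h[i] * h[i];
      for (int j = a; j < b; ++j) {
        double d = qs[j] - x[i];
        f[j] += exp(-(d * d) / hh) / total[i] / dn;
      }
    } else if (shape == 2) {
      double w = 1.0 / total[i] / dn;
      for (int j = a; j < b; ++j) f[j] += w;
    } else {
      double sh = 6.0 * h[i];
      for (int j = a; j < b; ++j) {
        double d = std::fabs(qs[j] - x[i]);
        f[j] += (1.0 - d / sh) / total[i] / dn;
      }
    }
  }
  return f;
}

// Nearest-neighbor distance statistics on sorted positions. For each i:
// column 0: k-th smallest |x_j - x_i| over j != i (multiset order statistic)
// column 1: distance to the nearest point strictly to the left (Inf if none)
// column 2: distance to the nearest point strictly to the right (Inf if none)
// Duplicates of x_i have distance 0 and lie strictly on neither side.
// [[Rcpp::export]]
NumericMatrix knn_core_cpp(NumericVector x, int k) {
  int n = x.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    int li = 1, ri = 1;
    double kth = R_PosInf;
    for (int t = 0; t < k; ++t) {
      double dl = (i - li >= 0) ? x[i] - x[i - li] : R_PosInf;
      double dr = (i + ri < n) ? x[i + ri] - x[i] : R_PosInf;
      if (dl <= dr) { kth = dl; ++li; } else { kth = dr; ++ri; }
    }
    out(i, 0) = kth;
    int j = i - 1;
    while (j >= 0 && x[j] == x[i]) --j;
    out(i, 1) = (j >= 0) ? x[i] - x[j] : R_PosInf;
    j = i + 1;
    while (j < n && x[j] == x[i]) ++j;
    out(i, 2) = (j < n) ? x[j] - x[i] : R_PosInf;
  }
  return out;
}
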