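#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double maxnorm_row(const NumericMatrix& m, int i, int j) {
  double d = 0.0;
  for (int c = 0; c < m.ncol(); ++c) {
    double v = std::fabs(m(i, c) - m(j, c));
    if (v > d) d = v;
  }
  return d;
}

// Kraskov-Stoegbauer-Grassberger MI estimator, variant 1, max-norm.
// Returns nats. O(n^2) exact neighbor search; fine for n up to ~10^4.
// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  const int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  std::vector<double> dx(n), dy(n), dj(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      dx[j] = maxnorm_row(x, i, j);
      dy[j] = maxnorm_row(y, i, j);
      dj[j] = std::max(dx[j], dy[j]);
    }
    dj[i] = R_PosInf;  // exclude self
    std::vector<double> tmp(dj);
    std::nth_element(tmp.begin(), tmp.begin() + (k - 1), tmp.end());
    const double eps = tmp[k - 1];  // distance to k-th neighbor
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}
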