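#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact multidimensional two-sample Kolmogorov-Smirnov (Peacock) discrepancy:
// the maximum over all 2^d axis orientations (<= or >= per axis) and all grid
// points formed by the pooled per-axis sample coordinates of |F1 - F2|.
// Counting is done with d-dimensional prefix sums over the pooled coordinate
// grid, so the statistic is exact (identical to full enumeration) at
// O(2^d * prod(m_k)) cost instead of O(2^d * prod(m_k) * n).

static inline std::vector<double> pooled_axis(const NumericMatrix& x,
                                              const NumericMatrix& y, int k) {
  std::vector<double> u;
  u.reserve(x.nrow() + y.nrow());
  for (int i = 0; i < x.nrow(); ++i) u.push_back(x(i, k));
  for (int i = 0; i < y.nrow(); ++i) u.push_back(y(i, k));
  std::sort(u.begin(), u.end());
  u.erase(std::unique(u.begin(), u.end()), u.end());
  return u;
}

static inline size_t axis_index(const std::vector<double>& u, double v) {
  return std::lower_bound(u.begin(), u.end(), v) - u.begin();
}

// [[Rcpp::export]]
double peacock_stat_cpp(NumericMatrix x, NumericMatrix y) {
  const int d = x.ncol();
  if (y.ncol() != d) stop("dimension mismatch");
  if (d < 1 || d > 3) stop("d must be 1, 2 or 3");
  const int n1 = x.nrow(), n2 = y.nrow();
  if (n1 < 1 || n2 < 1) stop("empty sample");

  std::vector<std::vector<double> > u(d);
  std::vector<size_t> m(d), stride(d);
  size_t total = 1;
  for (int k = 0; k < d; ++k) {
    u[k] = pooled_axis(x, y, k);
    m[k] = u[k].size();
    stride[k] = total;
    total *= m[k];
  }

  std::vector<double> h1(total, 0.0), h2(total, 0.0);
  for (int i = 0; i < n1; ++i) {
    size_t lin = 0;
    for (int k = 0; k < d; ++k) lin += stride[k] * axis_index(u[k], x(i, k));
    h1[lin] += 1.0;
  }
  for (int i = 0; i < n2; ++i) {
    size_t lin = 0;
    for (int k = 0; k < d; ++k) lin += stride[k] * axis_index(u[k], y(i, k));
    h2[lin] += 1.0;
  }

  double best = 0.0;
  std::vector<double> c1, c2;
  for (int orient = 0; orient < (1 << d); ++orient) {
    c1 = h1;
    c2 = h2;
    for (int k = 0; k < d; ++k) {
      const size_t st = stride[k], mk = m[k], block = st * mk;
      if (!(orient >> k & 1)) {
        // ascending prefix sum: counts of points with coord_k <= grid value
        for (size_t o = 0; o < total; o += block)
          for (size_t j = 1; j < mk; ++j) {
            const size_t b = o + j * st;
            for (size_t i = 0; i < st; ++i) {
              c1[b + i] += c1[b + i - st];
              c2[b + i] += c2[b + i - st];
            }
          }
      } else {
        // descending: counts of points with coord_k >= grid value
        for (size_t o = 0; o < total; o += block)
          for (size_t j = mk - 1; j-- > 0; ) {
            const size_t b = o + j * st;
            for (size_t i = 0; i < st; ++i) {
              c1[b + i] += c1[b + i + st];
              c2[b + i] += c2[b + i + st];
            }
          }
      }
    }
    for (size_t i = 0; i < total; ++i) {
      double diff = c1[i] / n1 - c2[i] / n2;
      if (diff < 0) diff = -diff;
      if (diff > best) best = diff;
    }
  }
  return best;
}
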