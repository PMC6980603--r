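#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher (2012). f is the input function, d the output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { v[k] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = (f[v[k]] == INF) ? INF : dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in cell units) from every cell to the nearest
// true cell of `mask`, measured centre to centre.
// [[Rcpp::export]]
NumericMatrix edt_cells(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix g(nr, nc);

  // column pass
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) g(i, j) = d[i];
  }
  // row pass
  std::vector<double> fr(nc), dr(nc);
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = g(i, j);
    dt1d(fr, dr);
    for (int j = 0; j < nc; ++j) out(i, j) = std::sqrt(dr[j]);
  }
  return out;
}
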