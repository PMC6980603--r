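#include <Rcpp.h>
#include <vector>
#include <array>
#include <random>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Tree storage: one row per node, columns
//   0 var   split variable, 1-based; 0 for a terminal node
//   1 thr   split threshold (midpoint of adjacent sorted unique values)
//   2 left  1-based node index of the left child (x < thr), 0 if terminal
//   3 right 1-based node index of the right child, 0 if terminal
//   4 imp   squared-error improvement of the split (0 for terminals)
//   5 value terminal value on the link scale (0 for internal nodes)
//   6 n     number of in-bag rows reaching the node

static const int C_VAR = 0, C_THR = 1, C_L = 2, C_R = 3, C_IMP = 4, C_VAL = 5, C_N = 6;

struct BestSplit {
  double gain = 0.0;
  int var = -1;          // 0-based
  double thr = 0.0;
};

struct OpenLeaf {
  int node;
  BestSplit best;
};

static inline double dev_bernoulli(const std::vector<double>& f,
                                   const NumericVector& y) {
  const int n = f.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double p = 1.0 / (1.0 + std::exp(-f[i]));
    if (p < 1e-12) p = 1e-12;
    if (p > 1.0 - 1e-12) p = 1.0 - 1e-12;
    s += y[i] * std::log(p) + (1.0 - y[i]) * std::log(1.0 - p);
  }
  return -2.0 * s / n;
}

// Best split for one leaf by exhaustive scan over all features, using the
// global per-feature sort orders. Exact gain ties break towards the
// variable whose name ranks first (name_rank), then the lowest threshold
// (scan order): deterministic and invariant under column permutation.
static BestSplit best_split(const NumericMatrix& X,
                            const std::vector<double>& r,
                            const std::vector<int>& node_of,
                            int leaf,
                            const std::vector<std::vector<int>>& ord,
                            int min_node,
                            const std::vector<int>& name_rank) {
  const int n = X.nrow();
  const int p = X.ncol();
  BestSplit best;
  // node totals, accumulated in row order so that the result is invariant
  // under permutation of the feature columns
  double s_tot = 0.0;
  int n_tot = 0;
  for (int i = 0; i < n; ++i)
    if (node_of[i] == leaf) { s_tot += r[i]; ++n_tot; }
  if (n_tot < 2 * min_node) return best;
  const double base = s_tot * s_tot / n_tot;

  for (int j = 0; j < p; ++j) {
    double sl = 0.0;
    int nl = 0;
    double prev = 0.0;
    bool have_prev = false;
    for (size_t t = 0; t < ord[j].size(); ++t) {
      int i = ord[j][t];
      if (node_of[i] != leaf) continue;
      double x = X(i, j);
      if (have_prev && x > prev && nl >= min_node && (n_tot - nl) >= min_node) {
        double sr = s_tot - sl;
        double gain = sl * sl / nl + sr * sr / (n_tot - nl) - base;
        bool better = gain > best.gain ||
          (gain == best.gain && best.var >= 0 &&
           name_rank[j] < name_rank[best.var]);
        if (best.var < 0 && gain <= 0) better = false;
        if (better && gain > 0) {
          best.gain = gain;
          best.var = j;
          best.thr = 0.5 * (prev + x);
        }
      }
      sl += r[i];
      ++nl;
      prev = x;
      have_prev = true;
    }
  }
  return best;
}

// Fit one regression tree to the gradient by greedy best-first splitting.
// Returns the node matrix; node_of maps each in-bag row to its terminal node
// (index into the matrix) on exit.
static NumericMatrix fit_tree(const NumericMatrix& X,
                              const std::vector<double>& r,
                              const std::vector<double>& h,
                              std::vector<int>& node_of, // -1 = out of bag
                              const std::vector<std::vector<int>>& ord,
                              int tc, int min_node,
                              const std::vector<int>& name_rank) {
  const int n = X.nrow();
  const int max_nodes = 2 * tc + 1;
  std::vector<std::array<double, 7>> nodes;
  nodes.reserve(max_nodes);
  nodes.push_back({0, 0, 0, 0, 0, 0, 0});

  // in-bag rows start at node 0
  int n_bag = 0;
  for (int i = 0; i < n; ++i) if (node_of[i] == 0) ++n_bag;
  nodes[0][C_N] = n_bag;

  std::vector<OpenLeaf> open;
  open.push_back({0, best_split(X, r, node_of, 0, ord, min_node, name_rank)});

  for (int split = 0; split < tc; ++split) {
    int pick = -1;
    double gmax = 1e-12;
    for (size_t q = 0; q < open.size(); ++q) {
      if (open[q].best.var >= 0 && open[q].best.gain > gmax) {
        gmax = open[q].best.gain;
        pick = (int)q;
      }
    }
    if (pick < 0) break;
    OpenLeaf leaf = open[pick];
    open.erase(open.begin() + pick);

    int li = (int)nodes.size();
    nodes.push_back({0, 0, 0, 0, 0, 0, 0});
    int ri = (int)nodes.size();
    nodes.push_back({0, 0, 0, 0, 0, 0, 0});

    nodes[leaf.node][C_VAR] = leaf.best.var + 1;
    nodes[leaf.node][C_THR] = leaf.best.thr;
    nodes[leaf.node][C_L] = li + 1;
    nodes[leaf.node][C_R] = ri + 1;
    nodes[leaf.node][C_IMP] = leaf.best.gain;

    int nle = 0, nri = 0;
    for (int i = 0; i < n; ++i) {
      if (node_of[i] != leaf.node) continue;
      if (X(i, leaf.best.var) < leaf.best.thr) { node_of[i] = li; ++nle; }
      else { node_of[i] = ri; ++nri; }
    }
    nodes[li][C_N] = nle;
    nodes[ri][C_N] = nri;

    open.push_back({li, best_split(X, r, node_of, li, ord, min_node, name_rank)});
    open.push_back({ri, best_split(X, r, node_of, ri, ord, min_node, name_rank)});
  }

  // terminal Newton step values for Bernoulli loss
  const int m = (int)nodes.size();
  std::vector<double> sr(m, 0.0), sh(m, 0.0);
  for (int i = 0; i < n; ++i) {
    if (node_of[i] < 0) continue;
    sr[node_of[i]] += r[i];
    sh[node_of[i]] += h[i];
  }
  for (int q = 0; q < m; ++q) {
    if (nodes[q][C_VAR] == 0)
      nodes[q][C_VAL] = (sh[q] > 1e-10) ? sr[q] / sh[q] : 0.0;
  }

  NumericMatrix T(m, 7);
  for (int q = 0; q < m; ++q)
    for (int c = 0; c < 7; ++c) T(q, c) = nodes[q][c];
  return T;
}

// Drop a feature row down a tree; ov1/ov2 (1-based, -1 = unused) override the
// value of a variable (partial-dependence evaluation).
static inline double tree_value(const NumericMatrix& T,
                                const NumericMatrix& X, int i,
                                int ov1, double v1, int ov2, double v2) {
  int node = 0;
  for (;;) {
    int v = (int)T(node, C_VAR);
    if (v == 0) return T(node, C_VAL);
    double x = (v == ov1) ? v1 : (v == ov2) ? v2 : X(i, v - 1);
    node = (x < T(node, C_THR)) ? (int)T(node, C_L) - 1 : (int)T(node, C_R) - 1;
  }
}

// Fit a single regression tree to gradient residuals (standalone surface
// for tests and tree-level work). inbag marks the rows used for fitting.
// [[Rcpp::export]]
NumericMatrix fit_tree_cpp(const NumericMatrix& X,
                           const NumericVector& residuals,
                           const NumericVector& hessians,
                           const LogicalVector& inbag,
                           int tc, int min_node,
                           const IntegerVector& name_rank) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> r(n), h(n);
  std::vector<int> node_of(n);
  for (int i = 0; i < n; ++i) {
    r[i] = residuals[i];
    h[i] = hessians[i];
    node_of[i] = inbag[i] ? 0 : -1;
  }
  std::vector<std::vector<int>> ord(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[j][i] = i;
    const double* col = &X(0, j);
    std::stable_sort(ord[j].begin(), ord[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }
  std::vector<int> nrank(name_rank.begin(), name_rank.end());
  return fit_tree(X, r, h, node_of, ord, tc, min_node, nrank);
}

// Forward-stagewise boosting with Bernoulli loss. Optionally continues from
// a previous state (init_link / valid_init) and tracks a held-out set.
// [[Rcpp::export]]
List boost_cpp(const NumericMatrix& X, const NumericVector& y,
               int tc, double lr, double bf, int min_node,
               int n_trees, int rng_seed,
               double intercept,
               const NumericVector& init_link,
               const NumericMatrix& Xvalid,
               const NumericVector& valid_init,
               const NumericVector& yvalid,
               const IntegerVector& name_rank) {
  const int n = X.nrow(), p = X.ncol();
  const int nv = Xvalid.nrow();
  std::mt19937 rng((unsigned)rng_seed);

  std::vector<double> f(n), fv(nv);
  if (init_link.size() == n) for (int i = 0; i < n; ++i) f[i] = init_link[i];
  else for (int i = 0; i < n; ++i) f[i] = intercept;
  if (nv > 0) {
    if (valid_init.size() == nv) for (int i = 0; i < nv; ++i) fv[i] = valid_init[i];
    else for (int i = 0; i < nv; ++i) fv[i] = intercept;
  }

  // global per-feature sort orders (stable, so ties keep row order)
  std::vector<std::vector<int>> ord(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[j][i] = i;
    const double* col = &X(0, j);
    std::stable_sort(ord[j].begin(), ord[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  int n_bag = (int)std::lround(bf * n);
  if (n_bag > n) n_bag = n;
  if (n_bag < std::min(n, 2 * min_node)) n_bag = std::min(n, 2 * min_node);

  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::vector<int> nrank(name_rank.begin(), name_rank.end());

  List trees(n_trees);
  NumericVector train_dev(n_trees), valid_dev(n_trees);
  std::vector<double> r(n), h(n);
  std::vector<int> node_of(n);

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-f[i]));
      r[i] = y[i] - pi;
      h[i] = pi * (1.0 - pi);
    }
    std::fill(node_of.begin(), node_of.end(), -1);
    if (n_bag < n) {
      std::shuffle(perm.begin(), perm.end(), rng);
      for (int q = 0; q < n_bag; ++q) node_of[perm[q]] = 0;
    } else {
      std::fill(node_of.begin(), node_of.end(), 0);
    }

    NumericMatrix T = fit_tree(X, r, h, node_of, ord, tc, min_node, nrank);
    trees[t] = T;

    for (int i = 0; i < n; ++i) f[i] += lr * tree_value(T, X, i, -1, 0, -1, 0);
    for (int i = 0; i < nv; ++i) fv[i] += lr * tree_value(T, Xvalid, i, -1, 0, -1, 0);

    train_dev[t] = dev_bernoulli(f, y);
    valid_dev[t] = (nv > 0) ? dev_bernoulli(fv, yvalid) : NA_REAL;
  }

  return List::create(_["trees"] = trees,
                      _["train_link"] = NumericVector(f.begin(), f.end()),
                      _["valid_link"] = NumericVector(fv.begin(), fv.end()),
                      _["train_dev"] = train_dev,
                      _["valid_dev"] = valid_dev);
}

// [[Rcpp::export]]
NumericVector predict_link_cpp(const List& trees, const NumericMatrix& X,
                               double intercept, double lr, int nt) {
  const int n = X.nrow();
  NumericVector f(n, intercept);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix T = trees[t];
    for (int i = 0; i < n; ++i) f[i] += lr * tree_value(T, X, i, -1, 0, -1, 0);
  }
  return f;
}

// Partial dependence: mean link-scale prediction over the training rows with
// one variable overwritten by each grid value.
// [[Rcpp::export]]
NumericVector pdp1_cpp(const List& trees, const NumericMatrix& X,
                       double intercept, double lr, int nt,
                       int var, const NumericVector& grid) {
  const int n = X.nrow(), g = grid.size();
  NumericVector out(g, intercept);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix T = trees[t];
    for (int k = 0; k < g; ++k) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i)
        acc += tree_value(T, X, i, var, grid[k], -1, 0);
      out[k] += lr * acc / n;
    }
  }
  return out;
}

// Two-variable partial-dependence surface on a lattice.
// [[Rcpp::export]]
NumericMatrix pdp2_cpp(const List& trees, const NumericMatrix& X,
                       double intercept, double lr, int nt,
                       int var_i, int var_j,
                       const NumericVector& grid_i, const NumericVector& grid_j) {
  const int n = X.nrow(), gi = grid_i.size(), gj = grid_j.size();
  NumericMatrix out(gi, gj);
  std::fill(out.begin(), out.end(), intercept);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix T = trees[t];
    for (int b = 0; b < gj; ++b)
      for (int a = 0; a < gi; ++a) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i)
          acc += tree_value(T, X, i, var_i, grid_i[a], var_j, grid_j[b]);
        out(a, b) += lr * acc / n;
      }
  }
  return out;
}
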