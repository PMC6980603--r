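#include <Rcpp.h>
#include <vector>
#include <random>
using namespace Rcpp;

// Seeded multi-source region growing on a grid. Seed cells are claimed up
// front; afterwards the class with the largest relative remaining capacity
// grows one cell at a time from a randomised frontier, so all classes fill
// their quotas roughly in lockstep and small classes are never starved.
// Once every capacity-respecting frontier is exhausted, remaining cells are
// claimed by whichever class can still reach them: the result is always a
// partition. Cells are 0-based ids i + j*nr. Returns 1-based class indices.
// [[Rcpp::export]]
IntegerMatrix grow_regions(int nr, int nc,
                           const IntegerMatrix& seed_cells, // (row, col, class) 1-based
                           const IntegerVector& capacity,
                           int rng_seed) {
  const int K = capacity.size();
  const int N = nr * nc;
  std::vector<int> assign(N, 0);
  std::vector<std::vector<int>> frontier(K);
  std::vector<int> count(K, 0);
  std::mt19937 rng((unsigned)rng_seed);
  int assigned = 0;

  auto claim = [&](int cell, int k) {
    assign[cell] = k + 1;
    ++count[k];
    ++assigned;
    int i = cell % nr, j = cell / nr;
    if (i > 0      && assign[cell - 1]  == 0) frontier[k].push_back(cell - 1);
    if (i < nr - 1 && assign[cell + 1]  == 0) frontier[k].push_back(cell + 1);
    if (j > 0      && assign[cell - nr] == 0) frontier[k].push_back(cell - nr);
    if (j < nc - 1 && assign[cell + nr] == 0) frontier[k].push_back(cell + nr);
  };

  for (int s = 0; s < seed_cells.nrow(); ++s) {
    int i = seed_cells(s, 0) - 1, j = seed_cells(s, 1) - 1, k = seed_cells(s, 2) - 1;
    int cell = i + j * nr;
    if (assign[cell] == 0) claim(cell, k);
  }

  std::uniform_real_distribution<double> U01(0.0, 1.0);
  while (assigned < N) {
    // class with the largest relative remaining quota (random tie-break);
    // fall back to any class that can still grow once quotas are filled
    int pick = -1;
    double best = -1.0;
    for (int k = 0; k < K; ++k) {
      if (frontier[k].empty() || count[k] >= capacity[k]) continue;
      double d = (double)(capacity[k] - count[k]) / (double)capacity[k]
                 + 1e-9 * U01(rng);
      if (d > best) { best = d; pick = k; }
    }
    if (pick < 0) {
      // a class may be under quota with a dead frontier (its patch got
      // enclosed): replant it at a random unassigned cell
      int replant = -1, deficit = 0;
      for (int k = 0; k < K; ++k)
        if (frontier[k].empty() && capacity[k] - count[k] > deficit) {
          deficit = capacity[k] - count[k];
          replant = k;
        }
      if (replant >= 0) {
        int cell = -1;
        std::uniform_int_distribution<int> UC(0, N - 1);
        for (int tries = 0; tries < 64 && cell < 0; ++tries) {
          int c = UC(rng);
          if (assign[c] == 0) cell = c;
        }
        if (cell < 0)
          for (int c = 0; c < N; ++c) if (assign[c] == 0) { cell = c; break; }
        claim(cell, replant);
        continue;
      }
      int nopen = 0;
      for (int k = 0; k < K; ++k) if (!frontier[k].empty()) ++nopen;
      if (nopen == 0) break; // unreachable cells (cannot occur on a grid)
      std::uniform_int_distribution<int> U(0, nopen - 1);
      int r = U(rng);
      for (int k = 0; k < K; ++k)
        if (!frontier[k].empty() && r-- == 0) { pick = k; break; }
    }
    // pop random frontier cells until one yields a claim
    std::vector<int>& fr = frontier[pick];
    while (!fr.empty()) {
      std::uniform_int_distribution<int> U(0, (int)fr.size() - 1);
      int idx = U(rng);
      int cell = fr[idx];
      fr[idx] = fr.back();
      fr.pop_back();
      if (assign[cell] == 0) { claim(cell, pick); break; }
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = assign[i + j * nr];
  return out;
}
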