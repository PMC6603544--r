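#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical matrix.
// connectivity: 4 or 8. Labels are 1..k in raster (column-major) discovery
// order of component roots; background is 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // dummy so labels are 1-based
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously visited neighbours in column-major order:
      // (i-1, j) same column; (i-1,j-1), (i,j-1), (i+1,j-1) previous column
      int best = 0;
      int cand[4];
      int ncand = 0;
      if (i > 0 && mask(i - 1, j)) cand[ncand++] = lab(i - 1, j);
      if (j > 0) {
        if (mask(i, j - 1)) cand[ncand++] = lab(i, j - 1);
        if (connectivity == 8) {
          if (i > 0 && mask(i - 1, j - 1)) cand[ncand++] = lab(i - 1, j - 1);
          if (i < nr - 1 && mask(i + 1, j - 1)) cand[ncand++] = lab(i + 1, j - 1);
        }
      }
      for (int k = 0; k < ncand; ++k)
        if (best == 0 || cand[k] < best) best = cand[k];
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < ncand; ++k) uf_union(parent, best, cand[k]);
      }
    }
  }

  // flatten and renumber consecutively
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  return lab;
}
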