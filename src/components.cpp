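#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass 4-connectivity labeling of a binary matrix.
// Returns integer matrix of component labels (1..k); 0 = background.
// [[Rcpp::export(name = ".label_cc_2d")]]
IntegerMatrix label_cc_2d(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      const int up = (i > 0 && mask(i - 1, j)) ? lab(i - 1, j) : 0;
      const int left = (j > 0 && mask(i, j - 1)) ? lab(i, j - 1) : 0;
      if (up == 0 && left == 0) {
        lab(i, j) = next;
        parent.push_back(next);
        ++next;
      } else if (up != 0 && left != 0) {
        lab(i, j) = std::min(up, left);
        uf_union(parent, up, left);
      } else {
        lab(i, j) = up != 0 ? up : left;
      }
    }
  }

  // flatten provisional labels to consecutive ids
  std::vector<int> remap(next, 0);
  int k = 0;
  for (int p = 1; p < next; ++p) {
    int r = uf_find(parent, p);
    if (remap[r] == 0) remap[r] = ++k;
    remap[p] = remap[r];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) != 0) lab(i, j) = remap[lab(i, j)];
  return lab;
}
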