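#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical mask.
// mask is H x W (rows = image rows, i.e. y); connectivity is 4 or 8.
// Returns an integer matrix of the same shape: 0 = background, components
// numbered 1..n in raster-scan order (top-to-bottom, left-to-right) of their
// first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // dummy so provisional labels start at 1

  // first pass: raster scan, link to previously-seen neighbours
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x)) continue;
      int neigh[4];
      int nn = 0;
      if (x > 0 && mask(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (y > 0 && mask(y - 1, x)) neigh[nn++] = lab(y - 1, x);
      if (connectivity == 8 && y > 0) {
        if (x > 0 && mask(y - 1, x - 1)) neigh[nn++] = lab(y - 1, x - 1);
        if (x < W - 1 && mask(y - 1, x + 1)) neigh[nn++] = lab(y - 1, x + 1);
      }
      if (nn == 0) {
        int nl = (int)parent.size();
        parent.push_back(nl);
        lab(y, x) = nl;
      } else {
        int m = neigh[0];
        for (int i = 1; i < nn; ++i) m = std::min(m, neigh[i]);
        lab(y, x) = m;
        for (int i = 0; i < nn; ++i) uf_union(parent, m, neigh[i]);
      }
    }
  }

  // second pass: resolve roots, renumber in raster order of first occurrence
  std::vector<int> final_label(parent.size(), 0);
  int next = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!lab(y, x)) continue;
      int r = uf_find(parent, lab(y, x));
      if (final_label[r] == 0) final_label[r] = ++next;
      lab(y, x) = final_label[r];
    }
  }
  return lab;
}
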