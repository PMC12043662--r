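// Connected-zone extraction for the gray-level size zone matrix: a single
// union-find pass over the quantized level map. Zones are maximal
// connected sets of equal-level pixels under 4- or 8-connectivity.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static int findRoot(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Returns a two-column integer matrix: (zone level, zone size), one row
// per connected zone. Level values are passed through unchanged.
// [[Rcpp::export(name = ".zoneTable")]]
IntegerMatrix zoneTable(const IntegerMatrix &lv, int connectivity) {
  const int h = lv.nrow(), w = lv.ncol(), n = h * w;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto unite = [&](int a, int b) {
    int ra = findRoot(parent, a), rb = findRoot(parent, b);
    if (ra != rb) parent[ra > rb ? ra : rb] = ra > rb ? rb : ra;
  };
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int idx = r + c * h;
      const int g = lv(r, c);
      if (r + 1 < h && lv(r + 1, c) == g) unite(idx, idx + 1);
      if (c + 1 < w && lv(r, c + 1) == g) unite(idx, idx + h);
      if (connectivity == 8) {
        if (r + 1 < h && c + 1 < w && lv(r + 1, c + 1) == g)
          unite(idx, idx + 1 + h);
        if (r > 0 && c + 1 < w && lv(r - 1, c + 1) == g)
          unite(idx, idx - 1 + h);
      }
    }
  }
  std::unordered_map<int, int> sizes;
  sizes.reserve(256);
  for (int i = 0; i < n; ++i) ++sizes[findRoot(parent, i)];
  IntegerMatrix out(sizes.size(), 2);
  int k = 0;
  for (const auto &kv : sizes) {
    out(k, 0) = lv[kv.first];
    out(k, 1) = kv.second;
    ++k;
  }
  colnames(out) = CharacterVector::create("level", "size");
  return out;
}
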