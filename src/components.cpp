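#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving; used for edge-connected regions of kept
// Delaunay triangles (called once per alpha evaluation, so it must be cheap)
// and for 8-connected components of raster foregrounds.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Connected components over n nodes restricted to `active` nodes, joined by
// the edge list (a[k], b[k]) (1-based); an edge is used only if both ends are
// active.  Returns integer labels 1..k for active nodes, 0 for inactive.
// [[Rcpp::export]]
List uf_components(int n, IntegerVector a, IntegerVector b, LogicalVector active) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int m = a.size();
  for (int k = 0; k < m; ++k) {
    int i = a[k] - 1, j = b[k] - 1;
    if (!active[i] || !active[j]) continue;
    int ri = uf_find(parent, i), rj = uf_find(parent, j);
    if (ri != rj) parent[ri] = rj;
  }
  IntegerVector labels(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++next;
    labels[i] = remap[r];
  }
  return List::create(_["labels"] = labels, _["n_components"] = next);
}
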