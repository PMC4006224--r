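#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Threshold-free cluster enhancement over an arbitrary voxel graph.
//
// TFCE(v) = sum_h e(h, v)^E * h^H * dh, where e(h, v) is the size of the
// connected component containing v among voxels with stat >= h. Thresholds
// are midpoints (s - 0.5) * dh for s = 1..ceil(max/dh), swept from high to
// low while voxels are activated incrementally into a union-find forest,
// so each sweep costs near-linear time in the number of active voxels.
//
// `nbr_ptr` / `nbr_idx` give the 0-based CSR adjacency of the voxels.

static int uf_find(std::vector<int> &parent, int v) {
  int root = v;
  while (parent[root] != root) root = parent[root];
  while (parent[v] != root) {
    int next = parent[v];
    parent[v] = root;
    v = next;
  }
  return root;
}

// [[Rcpp::export]]
NumericVector tfce_scores(NumericVector stat, IntegerVector nbr_ptr,
                          IntegerVector nbr_idx, double dh, double H,
                          double E) {
  const int n = stat.size();
  NumericVector out(n);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (stat[i] > hmax) hmax = stat[i];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  const int nsteps = (int)std::ceil(hmax / dh - 1e-12);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n, -1);
  std::vector<int> csize(n, 0);
  int pos = 0;

  for (int s = nsteps; s >= 1; --s) {
    const double h = (s - 0.5) * dh;
    while (pos < n && stat[ord[pos]] >= h) {
      const int v = ord[pos];
      parent[v] = v;
      csize[v] = 1;
      for (int e = nbr_ptr[v]; e < nbr_ptr[v + 1]; ++e) {
        const int w = nbr_idx[e];
        if (parent[w] < 0) continue;  // neighbour not active yet
        const int rv = uf_find(parent, v);
        const int rw = uf_find(parent, w);
        if (rv == rw) continue;
        if (csize[rv] >= csize[rw]) {
          parent[rw] = rv;
          csize[rv] += csize[rw];
        } else {
          parent[rv] = rw;
          csize[rw] += csize[rv];
        }
      }
      ++pos;
    }
    const double hh = std::pow(h, H) * dh;
    for (int q = 0; q < pos; ++q) {
      const int v = ord[q];
      out[v] += std::pow((double)csize[uf_find(parent, v)], E) * hh;
    }
  }
  return out;
}
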