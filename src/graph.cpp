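#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Single/multi-source Dijkstra on an undirected edge graph given in CSR form.
// Tie-break: among equal-length paths the predecessor with the smallest
// vertex id is kept, so extracted paths are deterministic.
//
// ptr:  length n+1, 0-based offsets into idx/w
// idx:  neighbour vertex ids (0-based)
// w:    edge lengths (mm)
// sources: 0-based source ids
// Returns list(dist = n x k matrix, pred = n x k integer matrix (0-based, -1 root/unreached))
// [[Rcpp::export]]
List dijkstra_csr(IntegerVector ptr, IntegerVector idx, NumericVector w,
                  IntegerVector sources) {
  const int n = ptr.size() - 1;
  const int k = sources.size();
  NumericMatrix dist(n, k);
  IntegerMatrix pred(n, k);
  const double INF = std::numeric_limits<double>::infinity();

  typedef std::pair<double, int> QE; // (dist, vertex)
  for (int s = 0; s < k; ++s) {
    std::vector<double> d(n, INF);
    std::vector<int> p(n, -1);
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > q;
    int src = sources[s];
    d[src] = 0.0;
    q.push(QE(0.0, src));
    while (!q.empty()) {
      QE top = q.top(); q.pop();
      double du = top.first; int u = top.second;
      if (du > d[u]) continue;
      for (int e = ptr[u]; e < ptr[u + 1]; ++e) {
        int v = idx[e];
        double nd = du + w[e];
        if (nd < d[v]) {
          d[v] = nd; p[v] = u;
          q.push(QE(nd, v));
        } else if (nd == d[v] && p[v] >= 0 && u < p[v]) {
          p[v] = u; // equal-length path through smaller predecessor id
        }
      }
    }
    for (int i = 0; i < n; ++i) { dist(i, s) = d[i]; pred(i, s) = p[i]; }
  }
  return List::create(_["dist"] = dist, _["pred"] = pred);
}

// 26-connected component labelling of a logical 3-D mask.
// mask: logical vector of length nx*ny*nz (column-major, x fastest)
// Returns integer vector of labels (0 = background, components numbered from 1
// in order of first voxel encountered in linear scan).
// [[Rcpp::export]]
IntegerVector label_components_26(LogicalVector mask, int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i0 = 0; i0 < n; ++i0) {
    if (!mask[i0] || lab[i0]) continue;
    ++next;
    stack.push_back(i0);
    lab[i0] = next;
    while (!stack.empty()) {
      R_xlen_t i = stack.back(); stack.pop_back();
      int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            R_xlen_t j = X + (R_xlen_t)nx * (Y + (R_xlen_t)ny * Z);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}
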