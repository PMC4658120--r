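#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Label the connected components of a 3D logical mask (6- or 26-connectivity)
// and return an integer array where the largest component keeps value 1 and
// everything else is 0. Empty masks are returned unchanged.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims,
                                    int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<int> label(n, 0);
  std::vector<R_xlen_t> comp_size;

  // neighbour offsets
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  int ncomp = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || label[s]) continue;
    ++ncomp;
    comp_size.push_back(0);
    label[s] = ncomp;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t v = q.front(); q.pop();
      ++comp_size[ncomp - 1];
      const int x = (int)(v % d1);
      const int y = (int)((v / d1) % d2);
      const int z = (int)(v / ((R_xlen_t)d1 * d2));
      for (size_t k = 0; k < ox.size(); ++k) {
        const int nx = x + ox[k], ny = y + oy[k], nz = z + oz[k];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d1 || ny >= d2 || nz >= d3) continue;
        const R_xlen_t w = nx + (R_xlen_t)d1 * (ny + (R_xlen_t)d2 * nz);
        if (mask[w] && !label[w]) { label[w] = ncomp; q.push(w); }
      }
    }
  }

  LogicalVector out(n, FALSE);
  if (ncomp == 0) { out.attr("dim") = dims; return out; }
  int best = 0;
  for (int c = 1; c < ncomp; ++c)
    if (comp_size[c] > comp_size[best]) best = c;
  for (R_xlen_t s = 0; s < n; ++s)
    out[s] = label[s] == best + 1;
  out.attr("dim") = dims;
  return out;
}

// For each row of `a`, the Euclidean distance to the nearest row of `b`
// (exhaustive; the point sets here are surface vertex sets of modest size).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = a(i, c) - b(j, c);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
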