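#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact (discrete) Gaussian transform: for every target point y_i,
//   G(y_i) = sum_j w_j * exp(-||y_i - x_j||^2 / h^2),
// by the direct double loop. Coordinates are in the aggregation grid's voxel
// units; h is the kernel width in the same units. Serves as the oracle for
// the IFGT path and as the exact aggregation backend on small grids.
// [[Rcpp::export]]
NumericVector cpp_gauss_exact(NumericMatrix targets, NumericMatrix sources,
                              NumericVector weights, double h) {
  const int m = targets.nrow(), n = sources.nrow();
  const double inv_h2 = 1.0 / (h * h);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double tx = targets(i, 0), ty = targets(i, 1), tz = targets(i, 2);
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dx = tx - sources(j, 0);
      const double dy = ty - sources(j, 1);
      const double dz = tz - sources(j, 2);
      acc += weights[j] * std::exp(-(dx * dx + dy * dy + dz * dz) * inv_h2);
    }
    out[i] = acc;
  }
  return out;
}

// Farthest-point (Gonzalez) clustering of the source points: starts from the
// first source and adds the point farthest from the current centers until
// either max_clusters is reached or the covering radius drops to radius_goal.
// Returns cluster assignment (0-based), centers, and per-cluster radii.
static void farthest_point_clustering(const NumericMatrix& x, int max_clusters,
                                      double radius_goal,
                                      std::vector<int>& assign,
                                      std::vector<double>& cx,
                                      std::vector<double>& cy,
                                      std::vector<double>& cz,
                                      std::vector<double>& rad) {
  const int n = x.nrow();
  assign.assign(n, 0);
  std::vector<double> dist2(n);
  cx.clear(); cy.clear(); cz.clear();
  cx.push_back(x(0, 0)); cy.push_back(x(0, 1)); cz.push_back(x(0, 2));
  for (int i = 0; i < n; ++i) {
    const double dx = x(i, 0) - cx[0], dy = x(i, 1) - cy[0], dz = x(i, 2) - cz[0];
    dist2[i] = dx * dx + dy * dy + dz * dz;
  }
  const double goal2 = radius_goal * radius_goal;
  while ((int)cx.size() < max_clusters) {
    int far = 0;
    double best = -1.0;
    for (int i = 0; i < n; ++i)
      if (dist2[i] > best) { best = dist2[i]; far = i; }
    if (best <= goal2) break;
    const double nx = x(far, 0), ny = x(far, 1), nz = x(far, 2);
    const int k = (int)cx.size();
    cx.push_back(nx); cy.push_back(ny); cz.push_back(nz);
    for (int i = 0; i < n; ++i) {
      const double dx = x(i, 0) - nx, dy = x(i, 1) - ny, dz = x(i, 2) - nz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dist2[i]) { dist2[i] = d2; assign[i] = k; }
    }
  }
  rad.assign(cx.size(), 0.0);
  for (int i = 0; i < n; ++i) {
    const double r = std::sqrt(dist2[i]);
    if (r > rad[assign[i]]) rad[assign[i]] = r;
  }
}

// Improved fast Gauss transform. The kernel is factorized about each cluster
// center c:
//   exp(-||y-x||^2/h^2) = exp(-||y-c||^2/h^2) exp(-||x-c||^2/h^2)
//                         * sum_a (2^|a|/a!) ((y-c)/h)^a ((x-c)/h)^a,
// truncated at total multi-index degree `order`. Source-side coefficients are
// accumulated per cluster; each target then evaluates only the clusters whose
// center lies within `cutoff + cluster radius` (farther clusters contribute
// below the requested accuracy).
// [[Rcpp::export]]
NumericVector cpp_gauss_ifgt(NumericMatrix targets, NumericMatrix sources,
                             NumericVector weights, double h, int order,
                             int max_clusters, double radius_goal, double cutoff) {
  const int m = targets.nrow(), n = sources.nrow();
  NumericVector out(m);
  if (n == 0) return out;

  std::vector<int> assign;
  std::vector<double> cx, cy, cz, rad;
  farthest_point_clustering(sources, max_clusters, radius_goal,
                            assign, cx, cy, cz, rad);
  const int K = (int)cx.size();
  const int p = order;

  // multi-indices (a,b,c) with a+b+c <= p, and constants 2^|a|/(a! b! c!)
  std::vector<int> ia, ib, ic;
  std::vector<double> cst;
  std::vector<double> fact(p + 1, 1.0);
  for (int i = 1; i <= p; ++i) fact[i] = fact[i - 1] * i;
  for (int a = 0; a <= p; ++a)
    for (int b = 0; b <= p - a; ++b)
      for (int c = 0; c <= p - a - b; ++c) {
        ia.push_back(a); ib.push_back(b); ic.push_back(c);
        cst.push_back(std::pow(2.0, a + b + c) / (fact[a] * fact[b] * fact[c]));
      }
  const int nterms = (int)ia.size();
  const double inv_h = 1.0 / h, inv_h2 = inv_h * inv_h;

  // source coefficients per cluster
  std::vector<double> coef((size_t)K * nterms, 0.0);
  std::vector<double> px(p + 1), py(p + 1), pz(p + 1);
  for (int j = 0; j < n; ++j) {
    const int k = assign[j];
    const double dx = (sources(j, 0) - cx[k]) * inv_h;
    const double dy = (sources(j, 1) - cy[k]) * inv_h;
    const double dz = (sources(j, 2) - cz[k]) * inv_h;
    const double g = weights[j] * std::exp(-(dx * dx + dy * dy + dz * dz));
    px[0] = py[0] = pz[0] = 1.0;
    for (int q = 1; q <= p; ++q) {
      px[q] = px[q - 1] * dx; py[q] = py[q - 1] * dy; pz[q] = pz[q - 1] * dz;
    }
    double* ck = &coef[(size_t)k * nterms];
    for (int t = 0; t < nterms; ++t)
      ck[t] += g * px[ia[t]] * py[ib[t]] * pz[ic[t]];
  }
  for (int k = 0; k < K; ++k) {
    double* ck = &coef[(size_t)k * nterms];
    for (int t = 0; t < nterms; ++t) ck[t] *= cst[t];
  }

  // target evaluation with per-cluster cutoff
  for (int i = 0; i < m; ++i) {
    const double tx = targets(i, 0), ty = targets(i, 1), tz = targets(i, 2);
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      const double dx = tx - cx[k], dy = ty - cy[k], dz = tz - cz[k];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double reach = cutoff + rad[k];
      if (d2 > reach * reach) continue;
      const double gx = dx * inv_h, gy = dy * inv_h, gz = dz * inv_h;
      const double g = std::exp(-d2 * inv_h2);
      px[0] = py[0] = pz[0] = 1.0;
      for (int q = 1; q <= p; ++q) {
        px[q] = px[q - 1] * gx; py[q] = py[q - 1] * gy; pz[q] = pz[q - 1] * gz;
      }
      const double* ck = &coef[(size_t)k * nterms];
      double s = 0.0;
      for (int t = 0; t < nterms; ++t)
        s += ck[t] * px[ia[t]] * py[ib[t]] * pz[ic[t]];
      acc += g * s;
    }
    out[i] = acc;
  }
  return out;
}
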