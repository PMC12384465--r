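#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Separable squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher 2012) with anisotropic voxel spacing. One pass of the 1-D
// lower-envelope transform per axis; distances are between voxel centers.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f at positions
// step * {0, 1, ..., n-1}; result written to d. Entries with f == INF
// contribute no parabola to the lower envelope.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double step) {
  std::vector<int> idx;
  idx.reserve(n);
  for (int q = 0; q < n; ++q)
    if (f[q] != INF) idx.push_back(q);
  if (idx.empty()) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  const int m = (int)idx.size();
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  int k = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (int t = 1; t < m; ++t) {
    int q = idx[t];
    double qs = q * step;
    double s;
    while (true) {
      double vs = v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (k > 0 && s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * step;
    while (z[k + 1] < qs) ++k;
    double diff = qs - v[k] * step;
    d[q] = diff * diff + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
Rcpp::NumericVector edt_cpp(Rcpp::LogicalVector feature,
                            Rcpp::IntegerVector dims,
                            Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    g[i] = (feature[i] == TRUE) ? 0.0 : INF;

  std::vector<double> f, d;

  // x axis
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, sx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y axis
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, sy);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)nx * j] = d[j];
    }
  // z axis
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = g[base + stride * k];
      dt1d(f, d, nz, sz);
      for (int k = 0; k < nz; ++k) g[base + stride * k] = d[k];
    }

  Rcpp::NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = (g[i] == INF) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// Exact test "distance from query point to the solid voxel region <= thr":
// the solid is a union of axis-aligned voxel cubes; distance to a cube has
// the closed form sqrt(sum(max(0, |p-c| - h)^2)). Queries are the thin
// uncertainty band left by the center-to-center EDT bounds, cubes are the
// solid's exposed (boundary) voxels.
// [[Rcpp::export(name = ".cube_dist_leq_cpp")]]
Rcpp::LogicalVector cube_dist_leq(Rcpp::NumericMatrix query,
                                  Rcpp::NumericMatrix cubes,
                                  Rcpp::NumericVector half,
                                  double thr) {
  const int nq = query.nrow(), nc = cubes.nrow();
  const double hx = half[0], hy = half[1], hz = half[2];
  const double thr2 = thr * thr;
  Rcpp::LogicalVector out(nq);
  std::vector<double> cx(nc), cy(nc), cz(nc);
  for (int j = 0; j < nc; ++j) {
    cx[j] = cubes(j, 0); cy[j] = cubes(j, 1); cz[j] = cubes(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    const double px = query(i, 0), py = query(i, 1), pz = query(i, 2);
    bool hit = false;
    for (int j = 0; j < nc; ++j) {
      double gx = std::fabs(px - cx[j]) - hx; if (gx < 0) gx = 0;
      double gy = std::fabs(py - cy[j]) - hy; if (gy < 0) gy = 0;
      double gz = std::fabs(pz - cz[j]) - hz; if (gz < 0) gz = 0;
      if (gx * gx + gy * gy + gz * gz <= thr2) { hit = true; break; }
    }
    out[i] = hit;
  }
  return out;
}
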