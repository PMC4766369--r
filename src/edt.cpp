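#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Exact Euclidean distance transform (squared), Felzenszwalb & Huttenlocher
// lower-envelope algorithm, applied separably along each axis with a
// per-axis voxel spacing, so anisotropic stacks are handled in physical
// units. Foreground seeds use a large finite sentinel instead of infinity
// to keep the envelope intersections well defined.

static const double LARGE = 1e30;
static const double INF = std::numeric_limits<double>::infinity();

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w2, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
Rcpp::NumericVector edt3d_cpp(Rcpp::LogicalVector mask,
                              Rcpp::IntegerVector dims,
                              Rcpp::NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? LARGE : 0.0;

  std::vector<double> f, d;
  f.resize(nx); d.resize(nx);
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = g[base + x];
      dt1d(f, d, w2, nx);
      for (int x = 0; x < nx; x++) g[base + x] = d[x];
    }
  f.resize(ny); d.resize(ny);
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, w2, ny);
      for (int y = 0; y < ny; y++) g[base + (R_xlen_t)y * nx] = d[y];
    }
  f.resize(nz); d.resize(nz);
  w2 = spacing[2] * spacing[2];
  R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = g[base + (R_xlen_t)z * plane];
      dt1d(f, d, w2, nz);
      for (int z = 0; z < nz; z++) g[base + (R_xlen_t)z * plane] = d[z];
    }

  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = g[i] >= LARGE ? R_PosInf : std::sqrt(g[i]);
  return out;
}
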