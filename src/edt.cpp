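#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance
// transform, generalised to anisotropic voxel spacing.  Distances are
// measured between voxel centers, in mm^2.

static const double INF = std::numeric_limits<double>::infinity();

// 1-D lower envelope of parabolas f(q) + (p-q)^2 * s^2 over sample index.
static void dt1d(const double* f, double* d, int n, double s2,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double sint;
    while (true) {
      int vk = v[k];
      sint = ((f[q] + (double)q * q * s2) - (f[vk] + (double)vk * vk * s2)) /
             (2.0 * s2 * (q - vk));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) {          // no sites on this line
    for (int p = 0; p < n; ++p) d[p] = INF;
    return;
  }
  k = 0;
  for (int p = 0; p < n; ++p) {
    while (z[k + 1] < p) ++k;
    double dq = (double)(p - v[k]);
    d[p] = dq * dq * s2 + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  double s2 = spacing[0] * spacing[0];
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, s2, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  s2 = spacing[1] * spacing[1];
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, s2, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  s2 = spacing[2] * spacing[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f.data(), d.data(), nz, s2, v, z);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
    }
  return out;
}
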