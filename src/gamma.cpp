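#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3-D gamma index with local dose normalization.  For each reference
// voxel above the low-dose cutoff, the evaluated dose is searched over a
// lattice of offsets (sorted by distance, early-terminated) with optional
// trilinear interpolation.

struct Offset { double dx, dy, dz, d2; };

static inline double trilinear(const NumericVector& a, int nx, int ny,
                               int nz, double fi, double fj, double fk,
                               bool& ok) {
  if (fi < 0 || fj < 0 || fk < 0 || fi > nx - 1 || fj > ny - 1 ||
      fk > nz - 1) { ok = false; return 0.0; }
  ok = true;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj),
      k0 = (int)std::floor(fk);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double u = fi - i0, v = fj - j0, w = fk - k0;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  double c000 = a[(R_xlen_t)k0 * nxy + (R_xlen_t)j0 * nx + i0];
  double c100 = a[(R_xlen_t)k0 * nxy + (R_xlen_t)j0 * nx + i1];
  double c010 = a[(R_xlen_t)k0 * nxy + (R_xlen_t)j1 * nx + i0];
  double c110 = a[(R_xlen_t)k0 * nxy + (R_xlen_t)j1 * nx + i1];
  double c001 = a[(R_xlen_t)k1 * nxy + (R_xlen_t)j0 * nx + i0];
  double c101 = a[(R_xlen_t)k1 * nxy + (R_xlen_t)j0 * nx + i1];
  double c011 = a[(R_xlen_t)k1 * nxy + (R_xlen_t)j1 * nx + i0];
  double c111 = a[(R_xlen_t)k1 * nxy + (R_xlen_t)j1 * nx + i1];
  double c00 = c000 * (1 - u) + c100 * u;
  double c10 = c010 * (1 - u) + c110 * u;
  double c01 = c001 * (1 - u) + c101 * u;
  double c11 = c011 * (1 - u) + c111 * u;
  double c0 = c00 * (1 - v) + c10 * v;
  double c1 = c01 * (1 - v) + c11 * v;
  return c0 * (1 - w) + c1 * w;
}

// [[Rcpp::export(name = ".gamma_search")]]
NumericVector gamma_search(NumericVector ref, NumericVector eval,
                           IntegerVector dims, NumericVector spacing,
                           double dose_frac, double dta_mm,
                           double cutoff_abs, NumericVector step_mm,
                           double max_radius_mm, bool interp) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n, NA_REAL);

  // offsets sorted by distance for early termination
  std::vector<Offset> offs;
  int mx = (int)std::floor(max_radius_mm / step_mm[0]);
  int my = (int)std::floor(max_radius_mm / step_mm[1]);
  int mz = (int)std::floor(max_radius_mm / step_mm[2]);
  if (nx == 1) mx = 0;
  if (ny == 1) my = 0;
  if (nz == 1) mz = 0;
  for (int a = -mx; a <= mx; ++a)
    for (int b = -my; b <= my; ++b)
      for (int c = -mz; c <= mz; ++c) {
        double dx = a * step_mm[0], dy = b * step_mm[1], dz = c * step_mm[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= max_radius_mm * max_radius_mm)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& p, const Offset& q) { return p.d2 < q.d2; });

  const double dta2 = dta_mm * dta_mm;
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t lin = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
        double R = ref[lin];
        if (!(R >= cutoff_abs)) continue;
        double denom = dose_frac * R;
        double best = R_PosInf;
        for (size_t q = 0; q < offs.size(); ++q) {
          double dterm = offs[q].d2 / dta2;
          if (dterm >= best) break;
          double fi = i + offs[q].dx / spacing[0];
          double fj = j + offs[q].dy / spacing[1];
          double fk = k + offs[q].dz / spacing[2];
          double E;
          bool ok;
          if (interp) {
            E = trilinear(eval, nx, ny, nz, fi, fj, fk, ok);
          } else {
            int ii = (int)std::lround(fi), jj = (int)std::lround(fj),
                kk = (int)std::lround(fk);
            ok = ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny &&
                 kk < nz;
            E = ok ? eval[(R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii] : 0.0;
          }
          if (!ok) continue;
          double dd = (E - R) / denom;
          double g2 = dterm + dd * dd;
          if (g2 < best) best = g2;
        }
        out[lin] = std::sqrt(best);
      }
  return out;
}
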