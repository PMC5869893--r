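#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pencil-beam dose deposition for one coplanar beam on a homogeneous
// water-equivalent body: exponential depth attenuation along the
// source-to-voxel ray, Gaussian lateral profile per beamlet measured in
// the isocenter plane (divergent projection).  Returns sparse triplets
// (kept-voxel row, beamlet column, Gy per unit weight).

static inline bool inside_mask(const LogicalVector& ext, int nx, int ny,
                               int nz, double x, double y, double z,
                               const NumericVector& org,
                               const NumericVector& sp) {
  int i = (int)std::lround((x - org[0]) / sp[0]);
  int j = (int)std::lround((y - org[1]) / sp[1]);
  int k = (int)std::lround((z - org[2]) / sp[2]);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
  return ext[(R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i];
}

// [[Rcpp::export(name = ".beam_dij_triplets")]]
List beam_dij_triplets(LogicalVector ext, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       IntegerVector kept,      // 0-based linear indices
                       NumericVector iso, double angle_deg, double sad,
                       double s0, double ds, int ncol_b,
                       double z0, double dz, int nrow_b,
                       double mu_mm, double sigma_mm, double step_mm,
                       double lateral_cut_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double th = angle_deg * M_PI / 180.0;
  // unit vector from isocenter toward source (coplanar, rotation about z)
  const double usx = std::sin(th), usy = std::cos(th);
  // beam axis (source -> iso) and in-plane lateral axis
  const double ax = -usx, ay = -usy;
  const double e1x = std::cos(th), e1y = -std::sin(th);
  const double Sx = iso[0] + sad * usx, Sy = iso[1] + sad * usy, Sz = iso[2];

  std::vector<int> ti, tj;
  std::vector<double> tx;
  const double two_s2 = 2.0 * sigma_mm * sigma_mm;
  const double cut2 = lateral_cut_mm * lateral_cut_mm;
  const R_xlen_t nk = kept.size();

  for (R_xlen_t m = 0; m < nk; ++m) {
    R_xlen_t lin = kept[m];
    int k = (int)(lin / ((R_xlen_t)nx * ny));
    int rem = (int)(lin - (R_xlen_t)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    double px = origin[0] + i * spacing[0];
    double py = origin[1] + j * spacing[1];
    double pz = origin[2] + k * spacing[2];

    double wx = px - Sx, wy = py - Sy, wz = pz - Sz;
    double zeta = wx * ax + wy * ay;            // depth along beam axis
    if (zeta <= 1.0) continue;                  // behind / at the source
    double mag = sad / zeta;                    // project to iso plane
    double s_iso = (wx * e1x + wy * e1y) * mag;
    double z_iso = wz * mag;

    // radiological depth: march from voxel toward the source
    double wlen = std::sqrt(wx * wx + wy * wy + wz * wz);
    double bx = -wx / wlen, by = -wy / wlen, bz = -wz / wlen;
    int nsteps = (int)(wlen / step_mm);
    double depth = 0.0;
    for (int q = 0; q < nsteps; ++q) {
      double t = (q + 0.5) * step_mm;
      double cx = px + bx * t, cy = py + by * t, cz = pz + bz * t;
      // stop once we leave the grid bounding box for good
      if (cx < origin[0] - spacing[0] || cy < origin[1] - spacing[1] ||
          cz < origin[2] - spacing[2] ||
          cx > origin[0] + nx * spacing[0] ||
          cy > origin[1] + ny * spacing[1] ||
          cz > origin[2] + nz * spacing[2]) break;
      if (inside_mask(ext, nx, ny, nz, cx, cy, cz, origin, spacing))
        depth += step_mm;
    }
    double att = std::exp(-mu_mm * depth);

    int clo = (int)std::ceil((s_iso - lateral_cut_mm - s0) / ds);
    int chi = (int)std::floor((s_iso + lateral_cut_mm - s0) / ds);
    int rlo = (int)std::ceil((z_iso - lateral_cut_mm - z0) / dz);
    int rhi = (int)std::floor((z_iso + lateral_cut_mm - z0) / dz);
    if (clo < 0) clo = 0;
    if (chi >= ncol_b) chi = ncol_b - 1;
    if (rlo < 0) rlo = 0;
    if (rhi >= nrow_b) rhi = nrow_b - 1;
    for (int r = rlo; r <= rhi; ++r) {
      double dzz = z_iso - (z0 + r * dz);
      for (int c = clo; c <= chi; ++c) {
        double dss = s_iso - (s0 + c * ds);
        double r2 = dss * dss + dzz * dzz;
        if (r2 > cut2) continue;
        double w = att * std::exp(-r2 / two_s2);
        ti.push_back((int)m + 1);                 // 1-based row
        tj.push_back(r * ncol_b + c + 1);         // 1-based beamlet col
        tx.push_back(w);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx));
}
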