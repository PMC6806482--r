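#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Global gamma-index minimization. Candidate displacements live on a regular
// sub-sampling lattice (default DTA/10) within a search radius (default
// 3 x DTA), visited in order of increasing distance so the scan can stop as
// soon as the distance term alone exceeds the running minimum. The
// evaluation distribution is interpolated bi/tri-linearly at candidate
// positions.

struct Off2 { double r2; double ox, oy; };
struct Off3 { double r2; double ox, oy, oz; };

static inline bool bilinear(const NumericMatrix &m, double x0, double y0,
                            double dx, double dy, double px, double py,
                            double &out) {
  double fx = (px - x0) / dx, fy = (py - y0) / dy;
  int i = (int)std::floor(fx), j = (int)std::floor(fy);
  // points on the upper grid edge belong to the last cell
  if (i + 1 == m.nrow() && fx <= m.nrow() - 1 + 1e-9) --i;
  if (j + 1 == m.ncol() && fy <= m.ncol() - 1 + 1e-9) --j;
  if (i < 0 || j < 0 || i + 1 >= m.nrow() || j + 1 >= m.ncol()) return false;
  double wx = fx - i, wy = fy - j;
  out = m(i, j) * (1 - wx) * (1 - wy) + m(i + 1, j) * wx * (1 - wy) +
        m(i, j + 1) * (1 - wx) * wy + m(i + 1, j + 1) * wx * wy;
  return true;
}

// [[Rcpp::export]]
NumericVector gamma2d_min_cpp(NumericVector ref_dose, NumericMatrix ref_xy,
                              NumericMatrix eval, double ex0, double ey0,
                              double edx, double edy, double dose_tol,
                              double dta, double search_radius, double sub_step) {
  int nref = ref_dose.size();
  NumericVector out(nref);
  int nmax = (int)std::floor(search_radius / sub_step);
  std::vector<Off2> offs;
  offs.reserve((2 * nmax + 1) * (2 * nmax + 1));
  double r2max = search_radius * search_radius;
  for (int a = -nmax; a <= nmax; ++a)
    for (int b = -nmax; b <= nmax; ++b) {
      double ox = a * sub_step, oy = b * sub_step, r2 = ox * ox + oy * oy;
      if (r2 <= r2max) offs.push_back({ r2, ox, oy });
    }
  std::sort(offs.begin(), offs.end(),
            [](const Off2 &u, const Off2 &v) { return u.r2 < v.r2; });
  double inv_tol2 = 1.0 / (dose_tol * dose_tol), inv_dta2 = 1.0 / (dta * dta);

  for (int r = 0; r < nref; ++r) {
    double dref = ref_dose[r], px = ref_xy(r, 0), py = ref_xy(r, 1);
    double best = R_PosInf;
    for (size_t c = 0; c < offs.size(); ++c) {
      double dist2 = offs[c].r2 * inv_dta2;
      if (dist2 >= best) break; // offsets sorted: nothing closer remains
      double dv;
      if (!bilinear(eval, ex0, ey0, edx, edy, px + offs[c].ox, py + offs[c].oy, dv))
        continue;
      double dd = dv - dref;
      double g2 = dd * dd * inv_tol2 + dist2;
      if (g2 < best) best = g2;
    }
    out[r] = R_finite(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}

static inline bool trilinear(const NumericVector &cube, int nx, int ny, int nz,
                             double x0, double y0, double z0, double dx,
                             double dy, double dz, double px, double py,
                             double pz, double &out) {
  double fx = (px - x0) / dx, fy = (py - y0) / dy, fz = (pz - z0) / dz;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i + 1 == nx && fx <= nx - 1 + 1e-9) --i;
  if (j + 1 == ny && fy <= ny - 1 + 1e-9) --j;
  if (k + 1 == nz && fz <= nz - 1 + 1e-9) --k;
  if (i < 0 || j < 0 || k < 0 || i + 1 >= nx || j + 1 >= ny || k + 1 >= nz)
    return false;
  double wx = fx - i, wy = fy - j, wz = fz - k;
  long n = (long)nx, nn = (long)nx * ny;
  long v000 = i + n * j + nn * k;
  double c00 = cube[v000] * (1 - wx) + cube[v000 + 1] * wx;
  double c10 = cube[v000 + n] * (1 - wx) + cube[v000 + n + 1] * wx;
  double c01 = cube[v000 + nn] * (1 - wx) + cube[v000 + nn + 1] * wx;
  double c11 = cube[v000 + nn + n] * (1 - wx) + cube[v000 + nn + n + 1] * wx;
  out = (c00 * (1 - wy) + c10 * wy) * (1 - wz) + (c01 * (1 - wy) + c11 * wy) * wz;
  return true;
}

// [[Rcpp::export]]
NumericVector gamma3d_min_cpp(NumericVector ref_dose, NumericMatrix ref_xyz,
                              NumericVector cube, IntegerVector dims,
                              NumericVector spacing, NumericVector origin,
                              double dose_tol, double dta,
                              double search_radius, double sub_step) {
  int nref = ref_dose.size();
  NumericVector out(nref);
  int nmax = (int)std::floor(search_radius / sub_step);
  std::vector<Off3> offs;
  double r2max = search_radius * search_radius;
  for (int a = -nmax; a <= nmax; ++a)
    for (int b = -nmax; b <= nmax; ++b)
      for (int c = -nmax; c <= nmax; ++c) {
        double ox = a * sub_step, oy = b * sub_step, oz = c * sub_step;
        double r2 = ox * ox + oy * oy + oz * oz;
        if (r2 <= r2max) offs.push_back({ r2, ox, oy, oz });
      }
  std::sort(offs.begin(), offs.end(),
            [](const Off3 &u, const Off3 &v) { return u.r2 < v.r2; });
  double inv_tol2 = 1.0 / (dose_tol * dose_tol), inv_dta2 = 1.0 / (dta * dta);
  int nx = dims[0], ny = dims[1], nz = dims[2];

  for (int r = 0; r < nref; ++r) {
    double dref = ref_dose[r];
    double px = ref_xyz(r, 0), py = ref_xyz(r, 1), pz = ref_xyz(r, 2);
    double best = R_PosInf;
    for (size_t c = 0; c < offs.size(); ++c) {
      double dist2 = offs[c].r2 * inv_dta2;
      if (dist2 >= best) break;
      double dv;
      if (!trilinear(cube, nx, ny, nz, origin[0], origin[1], origin[2],
                     spacing[0], spacing[1], spacing[2],
                     px + offs[c].ox, py + offs[c].oy, pz + offs[c].oz, dv))
        continue;
      double dd = dv - dref;
      double g2 = dd * dd * inv_tol2 + dist2;
      if (g2 < best) best = g2;
    }
    out[r] = R_finite(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}
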