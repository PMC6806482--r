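#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytical pencil-beam superposition: each spot contributes
// weight x IDD(WED(z)) x normalized 2D Gaussian with depth-dependent sigma.
// Spots sharing a depth profile (same energy layer and same central-axis
// column) are grouped; the R side supplies per-group IDD and sigma versus
// dose-grid z.

// [[Rcpp::export]]
NumericVector apb_deposit_cpp(IntegerVector dims, NumericVector spacing,
                              NumericVector origin,
                              NumericMatrix spots,   // x, y, weight, group (1-based)
                              NumericMatrix idd,     // nz x ngroups, Gy mm^2 / MU
                              NumericMatrix sigma,   // nz x ngroups, mm
                              double trunc_nsigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = spacing[0], dy = spacing[1];
  double x0 = origin[0], y0 = origin[1];
  NumericVector dose((long)nx * ny * nz);
  int nspots = spots.nrow();
  std::vector<double> gx(nx), gy(ny);

  for (int s = 0; s < nspots; ++s) {
    double sx = spots(s, 0), sy = spots(s, 1), w = spots(s, 2);
    int grp = (int)spots(s, 3) - 1;
    if (w <= 0) continue;
    for (int k = 0; k < nz; ++k) {
      double d = idd(k, grp);
      if (d <= 0) continue;
      double sg = sigma(k, grp);
      if (sg <= 0) continue;
      double inv2s2 = 1.0 / (2.0 * sg * sg);
      double norm = 1.0 / (2.0 * M_PI * sg * sg);
      double rad = trunc_nsigma * sg;
      int i0 = (int)std::ceil((sx - rad - x0) / dx), i1 = (int)std::floor((sx + rad - x0) / dx);
      int j0 = (int)std::ceil((sy - rad - y0) / dy), j1 = (int)std::floor((sy + rad - y0) / dy);
      if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
      if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
      if (i0 > i1 || j0 > j1) continue;
      for (int i = i0; i <= i1; ++i) {
        double ddx = x0 + i * dx - sx;
        gx[i] = std::exp(-ddx * ddx * inv2s2);
      }
      for (int j = j0; j <= j1; ++j) {
        double ddy = y0 + j * dy - sy;
        gy[j] = std::exp(-ddy * ddy * inv2s2);
      }
      double amp = w * d * norm;
      long base = (long)nx * ny * k;
      for (int j = j0; j <= j1; ++j) {
        double a = amp * gy[j];
        long row = base + (long)nx * j;
        for (int i = i0; i <= i1; ++i) dose[row + i] += a * gx[i];
      }
    }
  }
  return dose;
}
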