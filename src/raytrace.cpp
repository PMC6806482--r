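#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel raytracing (Amanatides-Woo): accumulates segment-length x RSP
// through the material grid, i.e. water-equivalent depth along the ray.

// [[Rcpp::export]]
List wed_ray_cpp(IntegerVector mat, IntegerVector dims, NumericVector spacing,
                 NumericVector origin, NumericVector mat_rsp,
                 NumericVector entry, NumericVector direction,
                 double geometric_depth) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double xmin = origin[0] - 0.5 * dx, ymin = origin[1] - 0.5 * dy, zmin = origin[2] - 0.5 * dz;
  double xmax = xmin + nx * dx, ymax = ymin + ny * dy, zmax = zmin + nz * dz;
  double px = entry[0], py = entry[1], pz = entry[2];
  double ux = direction[0], uy = direction[1], uz = direction[2];
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;

  // clip ray to the grid box [t0, t1]
  double t0 = 0.0, t1 = geometric_depth;
  const double lo[3] = { xmin, ymin, zmin }, hi[3] = { xmax, ymax, zmax };
  const double pp[3] = { px, py, pz }, uu[3] = { ux, uy, uz };
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(uu[a]) < 1e-12) {
      if (pp[a] < lo[a] || pp[a] >= hi[a]) t0 = t1 + 1.0;
    } else {
      double ta = (lo[a] - pp[a]) / uu[a], tb = (hi[a] - pp[a]) / uu[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) {
    return List::create(_["wed"] = 0.0, _["hit"] = false, _["geom_in_grid"] = 0.0);
  }

  const double eps = 1e-12;
  double t = t0 + eps;
  double wed = 0.0;
  while (t < t1 - eps) {
    double cx = px + ux * t, cy = py + uy * t, cz = pz + uz * t;
    int i = (int)std::floor((cx - xmin) / dx);
    int j = (int)std::floor((cy - ymin) / dy);
    int k = (int)std::floor((cz - zmin) / dz);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) break;
    // distance to next voxel boundary along the ray
    double tnext = t1;
    if (ux > eps)  tnext = std::min(tnext, (xmin + (i + 1) * dx - px) / ux);
    if (ux < -eps) tnext = std::min(tnext, (xmin + i * dx - px) / ux);
    if (uy > eps)  tnext = std::min(tnext, (ymin + (j + 1) * dy - py) / uy);
    if (uy < -eps) tnext = std::min(tnext, (ymin + j * dy - py) / uy);
    if (uz > eps)  tnext = std::min(tnext, (zmin + (k + 1) * dz - pz) / uz);
    if (uz < -eps) tnext = std::min(tnext, (zmin + k * dz - pz) / uz);
    if (tnext <= t) tnext = t + eps;
    double seg = std::min(tnext, t1) - t;
    long v = (long)i + (long)nx * ((long)j + (long)ny * k);
    wed += seg * mat_rsp[mat[v]];
    t = tnext + eps;
  }
  return List::create(_["wed"] = wed, _["hit"] = true, _["geom_in_grid"] = t1 - t0);
}

// WED profile down a +z column at lateral position (x, y): cumulative WED at
// each dose-grid z center, measured from the grid's upstream face.
// [[Rcpp::export]]
NumericVector wed_column_cpp(IntegerVector mat, IntegerVector dims,
                             NumericVector spacing, NumericVector origin,
                             NumericVector mat_rsp, double x, double y,
                             NumericVector z_centers) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double xmin = origin[0] - 0.5 * dx, ymin = origin[1] - 0.5 * dy, zmin = origin[2] - 0.5 * dz;
  int i = (int)std::floor((x - xmin) / dx);
  int j = (int)std::floor((y - ymin) / dy);
  int nq = z_centers.size();
  NumericVector out(nq);
  if (i < 0 || i >= nx || j < 0 || j >= ny) {
    for (int q = 0; q < nq; ++q) out[q] = NA_REAL;
    return out;
  }
  // cumulative WED at phantom-voxel boundaries
  std::vector<double> cum(nz + 1, 0.0);
  for (int k = 0; k < nz; ++k) {
    long v = (long)i + (long)nx * ((long)j + (long)ny * k);
    cum[k + 1] = cum[k] + dz * mat_rsp[mat[v]];
  }
  for (int q = 0; q < nq; ++q) {
    double depth = z_centers[q] - zmin; // geometric depth from upstream face
    if (depth <= 0) { out[q] = 0.0; continue; }
    double fk = depth / dz;
    int k = (int)fk;
    if (k >= nz) out[q] = cum[nz];
    else out[q] = cum[k] + (fk - k) * (cum[k + 1] - cum[k]);
  }
  return out;
}
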