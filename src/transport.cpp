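#include <Rcpp.h>
#include "pqa_physics.h"
#include "pqa_rng.h"
using namespace Rcpp;

// Condensed-history Class II proton transport on a voxel grid.
//
// Primaries are sampled from the plan's weighted spot list, started on the
// upstream face of the grid, and stepped until they stop, leave the grid, or
// fall below the transport cutoff. Soft interactions per step: exact
// Bragg-Kleeman mean energy loss, Bohr (Gaussian) energy-loss straggling,
// Highland (Gaussian) multiple Coulomb scattering applied at a midpoint
// hinge. Hard nonelastic interactions are sampled from the tabulated
// macroscopic cross section; on interaction the primary is replaced by a
// secondary proton (Class II transport continues), deuteron/alpha energy is
// deposited along straight-line CSDA segments, neutral energy escapes, and
// heavy-recoil energy is deposited locally. Delta electrons are not
// transported (local deposition). Dose is tallied as dose-to-water.

struct Grid {
  int nx, ny, nz;
  double dx, dy, dz, idx_, idy_, idz_;
  double x0, y0, z0;       // center of voxel [0,0,0]
  double xmin, ymin, zmin; // outer edges
  double xmax, ymax, zmax;

  void init(IntegerVector dims, NumericVector spacing, NumericVector origin) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    dx = spacing[0]; dy = spacing[1]; dz = spacing[2];
    idx_ = 1.0 / dx; idy_ = 1.0 / dy; idz_ = 1.0 / dz;
    x0 = origin[0]; y0 = origin[1]; z0 = origin[2];
    xmin = x0 - 0.5 * dx; ymin = y0 - 0.5 * dy; zmin = z0 - 0.5 * dz;
    xmax = xmin + nx * dx; ymax = ymin + ny * dy; zmax = zmin + nz * dz;
  }
  inline bool inside(double x, double y, double z) const {
    return x >= xmin && x < xmax && y >= ymin && y < ymax && z >= zmin && z < zmax;
  }
  // z-fastest internal layout: particles travel along +z, so deposits and
  // material lookups walk contiguous memory
  inline long idx(double x, double y, double z) const {
    int i = (int)((x - xmin) * idx_);
    int j = (int)((y - ymin) * idy_);
    int k = (int)((z - zmin) * idz_);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return -1;
    if (x < xmin || y < ymin || z < zmin) return -1;
    return (long)k + (long)nz * ((long)i + (long)nx * j);
  }
};

struct Tally {
  std::vector<float> batch;  // current batch, water-equivalent MeV (weighted)
  double q;                  // statistical weight of the current history
  double deposited;          // weighted MeV, conservation ledger
  double escaped;            // weighted MeV
  double injected;           // weighted MeV entering the grid
};

static inline void rotate_dir(double &ux, double &uy, double &uz,
                              double tx, double ty) {
  // apply small projected deflections tx, ty in a basis orthogonal to u;
  // renormalization uses |u + tx e1 + ty e2|^2 = 1 + tx^2 + ty^2 exactly,
  // expanded to second order (deflections are well below 0.3 rad)
  double e1x, e1y, e1z;
  if (std::fabs(uz) < 0.99) { // e1 along z-hat x u
    double inv = 1.0 / std::sqrt(ux * ux + uy * uy);
    e1x = -uy * inv; e1y = ux * inv; e1z = 0.0;
  } else {                    // e1 along x-hat x u
    double inv = 1.0 / std::sqrt(uz * uz + uy * uy);
    e1x = 0.0; e1y = uz * inv; e1z = -uy * inv;
  }
  double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z, e2z = ux * e1y - uy * e1x;
  ux += tx * e1x + ty * e2x;
  uy += tx * e1y + ty * e2y;
  uz += tx * e1z + ty * e2z;
  double ss = tx * tx + ty * ty;
  double n = 1.0 - 0.5 * ss + 0.375 * ss * ss;
  ux *= n; uy *= n; uz *= n;
}

static inline void rotate_polar(double &ux, double &uy, double &uz,
                                double cth, double phi) {
  // exact rotation of u by polar angle acos(cth), azimuth phi
  double ax, ay, az;
  if (std::fabs(uz) < 0.99) { ax = 0; ay = 0; az = 1; } else { ax = 1; ay = 0; az = 0; }
  double e1x = ay * uz - az * uy, e1y = az * ux - ax * uz, e1z = ax * uy - ay * ux;
  double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n1; e1y /= n1; e1z /= n1;
  double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z, e2z = ux * e1y - uy * e1x;
  double sth = std::sqrt(std::max(0.0, 1.0 - cth * cth));
  double cx = sth * std::cos(phi), cy = sth * std::sin(phi);
  ux = cth * ux + cx * e1x + cy * e2x;
  uy = cth * uy + cx * e1y + cy * e2y;
  uz = cth * uz + cx * e1z + cy * e2z;
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
}

// Deposit energy along a straight segment. The energy lost over a step is
// apportioned to the crossed voxels in proportion to rsp x length, so the
// dose-to-water per unit path is uniform along the segment and boundary
// crossings between dense and near-void media stay exact. Returns the
// energy that escaped the grid.
struct PqaSub { long v; double len; double rsp; };

struct PqaVox { float cap; float rsp; int mat; };

// heterogeneous region: the step ends at the voxel boundary so the energy
// loss is evaluated in a single material
__attribute__((noinline)) static double boundary_cap(
    const Grid &g, double minsp, double x, double y, double z,
    double ux, double uy, double uz) {
  double tb = 1e30;
  if (ux > 1e-9)  tb = std::min(tb, (g.xmin + (std::floor((x - g.xmin) * g.idx_) + 1) * g.dx - x) / ux);
  if (ux < -1e-9) tb = std::min(tb, (g.xmin + std::floor((x - g.xmin) * g.idx_) * g.dx - x) / ux);
  if (uy > 1e-9)  tb = std::min(tb, (g.ymin + (std::floor((y - g.ymin) * g.idy_) + 1) * g.dy - y) / uy);
  if (uy < -1e-9) tb = std::min(tb, (g.ymin + std::floor((y - g.ymin) * g.idy_) * g.dy - y) / uy);
  if (uz > 1e-9)  tb = std::min(tb, (g.zmin + (std::floor((z - g.zmin) * g.idz_) + 1) * g.dz - z) / uz);
  if (uz < -1e-9) tb = std::min(tb, (g.zmin + std::floor((z - g.zmin) * g.idz_) * g.dz - z) / uz);
  double cap = std::min(2.0 * minsp, tb + 1e-6);
  return cap < 1e-6 ? 1e-6 : cap;
}

__attribute__((noinline)) static double deposit_segment(const Grid &g, const std::vector<PqaVox> &vox,
                              const std::vector<double> &tly, Tally &t,
                              double x, double y, double z,
                              double ux, double uy, double uz,
                              double length, double edep, double wet) {
  // Deposits `edep` (true MeV, lost over a path of water-equivalent
  // thickness `wet`) along the segment. Dose-to-water per unit path is
  // edep/wet -- fixed by the step physics, so voxels grazed across material
  // seams can never receive amplified dose -- while the true-MeV ledger is
  // apportioned by length.
  if (length <= 0 || edep <= 0) {
    long v = g.idx(x, y, z);
    if (v >= 0 && edep > 0) {
      double r = vox[v].rsp;
      double sup = r >= 0.25 ? 1.0 : r * 4.0;
      t.batch[v] += (float)(t.q * edep / tly[vox[v].mat] * sup);
      t.deposited += t.q * edep;
      return 0.0;
    }
    return edep;
  }
  if (wet <= 1e-12) wet = 1e-12;
  double dwl = edep / wet;      // water-equivalent MeV per mm of path
  double del = edep / length;   // true MeV per mm of path
  // near-void voxels report suppressed dose (the dose-to-water conversion
  // degenerates there); factor is continuous at the 0.25 threshold
  #define PQA_SUP(r) ((r) >= 0.25f ? 1.0 : (double)(r) * 4.0)
  double esc = 0.0;
  if (std::fabs(ux) * length < 0.4 * g.dx && std::fabs(uy) * length < 0.4 * g.dy &&
      uz > 0.5) {
    // near-axial fast path: whole segment lies in one lateral column
    double xm = x + ux * 0.5 * length, ym = y + uy * 0.5 * length;
    int i = (int)((xm - g.xmin) * g.idx_);
    int j = (int)((ym - g.ymin) * g.idy_);
    if (xm >= g.xmin && ym >= g.ymin && i >= 0 && i < g.nx && j >= 0 && j < g.ny) {
      long base = (long)g.nz * ((long)i + (long)g.nx * j);
      double zend = z + uz * length;
      int k0 = (int)std::floor((z - g.zmin) * g.idz_);
      int k1 = (int)std::floor((zend - g.zmin) * g.idz_);
      double invuz = 1.0 / uz;
      double covered = 0.0;
      for (int k = k0; k <= k1; ++k) {
        double zlo = g.zmin + k * g.dz, zhi = zlo + g.dz;
        double ov = (std::min(zhi, zend) - std::max(zlo, z)) * invuz;
        if (ov <= 0) continue;
        covered += ov;
        if (k < 0 || k >= g.nz) { esc += del * ov; continue; }
        long v = base + k;
        t.batch[v] += (float)(t.q * dwl * ov * PQA_SUP(vox[v].rsp));
        t.deposited += t.q * del * ov;
      }
      if (length - covered > 1e-9) esc += del * (length - covered);
    } else esc = edep;
    return esc;
  }
  if (std::fabs(uz) > 0.3) {
    // forward-directed: walk the z-voxel boundaries
    double invuz = 1.0 / uz;
    double t0 = 0.0;
    int guard = 0;
    while (t0 < length - 1e-12 && ++guard < 200) {
      double zc = z + uz * t0;
      int k = (int)std::floor((zc - g.zmin) * g.idz_);
      double znext = g.zmin + (uz > 0 ? (double)(k + 1) : (double)k) * g.dz;
      double tnext = (znext - z) * invuz;
      if (tnext <= t0 + 1e-12) tnext = t0 + 1e-9;
      if (tnext > length) tnext = length;
      double tm = 0.5 * (t0 + tnext), dl = tnext - t0;
      long v = g.idx(x + ux * tm, y + uy * tm, z + uz * tm);
      if (v >= 0) {
        t.batch[v] += (float)(t.q * dwl * dl * PQA_SUP(vox[v].rsp));
        t.deposited += t.q * del * dl;
      } else esc += del * dl;
      t0 = tnext;
    }
    if (t0 < length) esc += del * (length - t0);
    return esc;
  }
  // oblique tracks: sub-voxel chunks
  double chunk = std::min(g.dx, std::min(g.dy, g.dz));
  int n = (int)std::ceil(length / chunk);
  if (n < 1) n = 1;
  if (n > 200) n = 200;
  double dl = length / n;
  for (int c = 0; c < n; ++c) {
    double sc = (c + 0.5) * dl;
    long v = g.idx(x + ux * sc, y + uy * sc, z + uz * sc);
    if (v >= 0) {
      t.batch[v] += (float)(t.q * dwl * dl * PQA_SUP(vox[v].rsp));
      t.deposited += t.q * del * dl;
    } else esc += del * dl;
  }
  if (n == 200 && length - 200.0 * dl > 1e-9) esc += del * (length - 200.0 * dl);
  return esc;
}

static inline double sample_forward_cos(PqaRng &rng, double kappa) {
  // density proportional to exp(kappa * cos(theta)) on [-1, 1]
  double u = rng.unif();
  return 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
}

// [[Rcpp::export]]
List mc_transport_cpp(IntegerVector mat, IntegerVector dims,
                      NumericVector spacing, NumericVector origin,
                      NumericVector mat_rsp, NumericVector mat_x0mm,
                      NumericVector mat_nucscale,
                      NumericMatrix spots, // columns x, y, energy, weight, sigma_air
                      double rs_wet, List phys_list,
                      double open_step_mm,
                      double shifter_step_mm, double range_step_frac,
                      int batch_hist, int n_batches,
                      double target_unc, int min_batches, int max_batches,
                      double seed, double dose_threshold_frac) {
  PqaPhysics ph; ph.build(phys_list);
  Grid g; g.init(dims, spacing, origin);
  long nvox = (long)g.nx * g.ny * g.nz;
  double minsp = std::min(spacing[0], std::min(spacing[1], spacing[2]));

  // z-fastest internal copies (input arrays are x-fastest R arrays)
  std::vector<int> matz(nvox);
  std::vector<double> rspv(mat_rsp.begin(), mat_rsp.end());
  std::vector<double> tly(rspv.size()); // tally divisor, floored in near-void media
  for (size_t q = 0; q < rspv.size(); ++q) tly[q] = std::max(rspv[q], 0.25);
  std::vector<double> x0v(mat_x0mm.begin(), mat_x0mm.end());
  std::vector<double> nucv(mat_nucscale.begin(), mat_nucscale.end());
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long vr = (long)i + (long)g.nx * ((long)j + (long)g.ny * k);
        long vz = (long)k + (long)g.nz * ((long)i + (long)g.nx * j);
        matz[vz] = mat[vr];
      }
  // per-voxel step cap: the guaranteed single-material length ahead along +z
  // (forward transport), reduced over the 3x3 lateral neighborhood to cover
  // small lateral drift; zero forces boundary-exact stepping
  std::vector<float> freez(nvox), capz(nvox);
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) {
      long col = (long)g.nz * ((long)i + (long)g.nx * j);
      freez[col + g.nz - 1] = 0.0f;
      for (int k = g.nz - 2; k >= 0; --k)
        freez[col + k] = matz[col + k + 1] == matz[col + k]
          ? freez[col + k + 1] + (float)g.dz : 0.0f;
    }
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) {
      long col = (long)g.nz * ((long)i + (long)g.nx * j);
      for (int k = 0; k < g.nz; ++k) {
        float f = freez[col + k];
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= g.nx || jj >= g.ny) { f = 0.0f; continue; }
            long vv = (long)k + (long)g.nz * ((long)ii + (long)g.nx * jj);
            if (matz[vv] != matz[col + k]) f = 0.0f;
            else if (freez[vv] < f) f = freez[vv];
          }
        capz[col + k] = std::min(f, (float)open_step_mm);
      }
    }
  std::vector<PqaVox> vox(nvox);
  for (long v = 0; v < nvox; ++v)
    vox[v] = { capz[v], (float)rspv[matz[v]], matz[v] };

  Tally t; t.batch.assign(nvox, 0.0);
  t.deposited = 0; t.escaped = 0; t.injected = 0;
  std::vector<double> sum(nvox, 0.0), sumsq(nvox, 0.0);

  int nspots = spots.nrow();
  double tw = 0;
  for (int s = 0; s < nspots; ++s) tw += spots(s, 3);
  if (tw <= 0) stop("plan has zero total weight");
  // stratified per-spot history allocation: processing one spot's histories
  // together keeps the tally working set small, and fixing the per-spot
  // counts removes the inter-spot Poisson variance
  std::vector<int> n_spot(nspots);
  std::vector<double> q_spot(nspots);
  long H = 0;
  for (int s = 0; s < nspots; ++s) {
    double e = spots(s, 3) / tw * batch_hist;
    n_spot[s] = std::max(1L, std::lround(e));
    H += n_spot[s];
  }
  for (int s = 0; s < nspots; ++s)
    q_spot[s] = spots(s, 3) / tw * (double)H / n_spot[s];

  uint64_t master = (uint64_t)seed;
  long n_steps = 0, n_bsteps = 0, n_subs = 0;
  PqaRng rng;
  long hist_global = 0;
  int b = 0;
  double agg_unc = NA_REAL;
  bool use_target = target_unc > 0;
  int run_batches = use_target ? max_batches : n_batches;

  for (b = 0; b < run_batches; ++b) {
    for (int lo = 0; lo < nspots; ++lo) {
    for (int h = 0; h < n_spot[lo]; ++h, ++hist_global) {
      rng.seed(master, (uint64_t)hist_global);
      t.q = q_spot[lo];
      double E = spots(lo, 2);
      double sig = spots(lo, 4);
      double x = spots(lo, 0) + sig * rng.norm();
      double y = spots(lo, 1) + sig * rng.norm();
      double z = g.zmin;
      double ux = 0, uy = 0, uz = 1;
      double cum_wet = 0;       // cumulative WET for the Highland profile
      double lambda = -std::log(rng.unif()); // nuclear mean free paths to go

      // --- upstream range shifter: water slab, straggling + nuclear, no
      // --- lateral transport (in-air spread is folded into sigma_air),
      // --- nothing tallied
      double rs_left = rs_wet;
      while (rs_left > 1e-9 && E > ph.cutoff_mev) {
        double Rres = ph.R_of_E(E);
        if (Rres <= rs_left) { E = 0; break; } // stops inside the shifter
        double L = std::min(std::min(shifter_step_mm, range_step_frac * Rres), rs_left);
        double Emid = ph.E_of_R(Rres - 0.5 * L);
        double Enew = ph.E_of_R(Rres - L);
        double dE = (E - Enew) + std::sqrt(ph.bohr_mev2_per_mm * L) * rng.norm();

        if (dE < 0) dE = 0; if (dE > E) dE = E;
        double tau = ph.sigma_nuc(Emid) * L;
        lambda -= tau;
        if (lambda <= 0) {
          // nonelastic interaction in the shifter: keep only the secondary
          // proton, everything else is absorbed upstream of the phantom
          double Eat = E - dE * std::min(1.0, std::max(0.0, (tau + lambda) / tau));
          E = ph.frac_p * Eat;
          lambda = -std::log(rng.unif());
        } else {
          E -= dE;
        }
        cum_wet += L;
        rs_left -= L;
      }
      if (E <= ph.cutoff_mev) continue; // never reached the phantom

      t.injected += t.q * E;

      // --- in-grid condensed-history loop (single particle; a nonelastic
      // --- interaction replaces the primary by its secondary proton)
      int guard = 0;
      while (++guard < 100000) {
        if (E <= ph.cutoff_mev) { // terminate, residual deposited locally
          long v = g.idx(x, y, z);
          if (v >= 0) { double r0 = vox[v].rsp; t.batch[v] += (float)(t.q * E / tly[vox[v].mat] * (r0 >= 0.25 ? 1.0 : r0 * 4.0)); t.deposited += t.q * E; }
          else t.escaped += t.q * E;
          break;
        }
        long v = g.idx(x, y, z);
        if (v < 0) { t.escaped += t.q * E; break; }
        int m = vox[v].mat;
        double rsp = vox[v].rsp;
        double Rres_w = ph.R_of_E(E);

        if (E <= ph.tail_emax) { // CSDA tail: residual range < ~2 mm of water
          if (rsp < 0.25) {
            // a slow proton in near-void media coasts out of the region of
            // interest; depositing its dose-to-water along a meter of air
            // would be pathological
            t.escaped += t.q * E;
            break;
          }
          double Lphys = Rres_w / rsp;
          t.escaped += t.q * deposit_segment(g, vox, tly, t, x, y, z, ux, uy, uz, Lphys, E, Rres_w);
          break;
        }

        double cap = vox[v].cap;
        ++n_steps;
        if (cap < 1.5 * minsp || uz < 0.7) {
          ++n_bsteps;
          // heterogeneous region: the step ends at the voxel boundary so the
          // energy loss is evaluated in a single material
          double tb = 1e30;
          if (ux > 1e-9)  tb = std::min(tb, (g.xmin + (std::floor((x - g.xmin) * g.idx_) + 1) * g.dx - x) / ux);
          if (ux < -1e-9) tb = std::min(tb, (g.xmin + std::floor((x - g.xmin) * g.idx_) * g.dx - x) / ux);
          if (uy > 1e-9)  tb = std::min(tb, (g.ymin + (std::floor((y - g.ymin) * g.idy_) + 1) * g.dy - y) / uy);
          if (uy < -1e-9) tb = std::min(tb, (g.ymin + std::floor((y - g.ymin) * g.idy_) * g.dy - y) / uy);
          if (uz > 1e-9)  tb = std::min(tb, (g.zmin + (std::floor((z - g.zmin) * g.idz_) + 1) * g.dz - z) / uz);
          if (uz < -1e-9) tb = std::min(tb, (g.zmin + std::floor((z - g.zmin) * g.idz_) * g.dz - z) / uz);
          cap = std::min(2.0 * minsp, tb + 1e-6);
          if (cap < 1e-6) cap = 1e-6;
        }
        double L = std::min(cap, range_step_frac * Rres_w / rsp);
        double Lwet = L * rsp;
        double Emid = ph.E_of_R(Rres_w - 0.5 * Lwet);
        double Enew = ph.E_of_R(Rres_w - Lwet);
        double dE_mean = E - Enew;
        double sigE = std::sqrt(ph.bohr_mev2_per_mm * rsp * L);
        if (sigE > 0.5 * dE_mean) sigE = 0.5 * dE_mean; // near-void media
        double dE = dE_mean + sigE * rng.norm();
        if (dE < 0) dE = 0; if (dE > E) dE = E;

        double tau = ph.sigma_nuc(Emid) * nucv[m] * L;
        // deuteron/alpha/heavy-recoil products have (sub-)millimeter ranges:
        // their energy share is tallied as an expected-value deposit along
        // the actually travelled track (unbiased for the mean dose, and it
        // removes the large point-deposit variance of analog lumps)
        double evloc = tau * ph.ev_local_frac * Emid;
        lambda -= tau;
        if (tau > 0 && lambda <= 0) {
          // hard nonelastic interaction at fraction f of the step
          double f = std::min(1.0, std::max(0.0, (tau + lambda) / tau));
          t.escaped += t.q * deposit_segment(g, vox, tly, t, x, y, z, ux, uy, uz,
                                             f * L, (dE + evloc) * f, f * Lwet);
          x += ux * f * L; y += uy * f * L; z += uz * f * L;
          cum_wet += f * Lwet;
          double Eat = E - dE * f;
          if (Eat < 0) Eat = 0;
          // neutrals: energy removed from the simulation
          t.escaped += t.q * ph.frac_neutral * Eat;
          // secondary proton continues under Class II transport
          E = ph.frac_p * Eat;
          rotate_polar(ux, uy, uz, sample_forward_cos(rng, ph.kappa),
                       6.283185307179586 * rng.unif());
          lambda = -std::log(rng.unif());
          if (E <= ph.cutoff_mev) {
            long vv = g.idx(x, y, z);
            if (vv >= 0) { double r0 = vox[vv].rsp; t.batch[vv] += (float)(t.q * E / tly[vox[vv].mat] * (r0 >= 0.25 ? 1.0 : r0 * 4.0)); t.deposited += t.q * E; }
            else t.escaped += t.q * E;
            break;
          }
          continue;
        }

        // soft step with midpoint hinge: deposit first half, deflect, second half
        double var = ph.pv2(Emid) * (ph.Gfun(cum_wet + Lwet) - ph.Gfun(cum_wet)) / Lwet
                     * (L / x0v[m]);
        if (var < 0) var = 0;
        double sth = std::sqrt(var);
        if (Rres_w < 20.0) {
          // near the Bragg peak the stopping power rises steeply across the
          // step: deposit the two halves with their exact CSDA energy split
          double w1 = dE_mean > 1e-12 ? (E - Emid) / dE_mean : 0.5;
          if (w1 < 0) w1 = 0; if (w1 > 1) w1 = 1;
          t.escaped += t.q * deposit_segment(g, vox, tly, t, x, y, z, ux, uy, uz,
                                             0.5 * L, (dE + evloc) * w1, 0.5 * Lwet);
          x += ux * 0.5 * L; y += uy * 0.5 * L; z += uz * 0.5 * L;
          rotate_dir(ux, uy, uz, sth * rng.norm(), sth * rng.norm());
          t.escaped += t.q * deposit_segment(g, vox, tly, t, x, y, z, ux, uy, uz,
                                             0.5 * L, (dE + evloc) * (1.0 - w1),
                                             0.5 * Lwet);
          x += ux * 0.5 * L; y += uy * 0.5 * L; z += uz * 0.5 * L;
        } else {
          double x0s = x, y0s = y, z0s = z;
          x += ux * 0.5 * L; y += uy * 0.5 * L; z += uz * 0.5 * L;
          rotate_dir(ux, uy, uz, sth * rng.norm(), sth * rng.norm());
          x += ux * 0.5 * L; y += uy * 0.5 * L; z += uz * 0.5 * L;
          // one deposit along the step chord (hinge deflections are
          // mrad-scale, so the chord stays within a fraction of a voxel of
          // the true path)
          double cx = x - x0s, cy = y - y0s, cz = z - z0s;
          double clen = std::sqrt(cx * cx + cy * cy + cz * cz);
          if (clen > 1e-12)
            t.escaped += t.q * deposit_segment(g, vox, tly, t, x0s, y0s, z0s,
                                               cx / clen, cy / clen, cz / clen,
                                               clen, dE + evloc, Lwet);
        }
        cum_wet += Lwet;
        E -= dE;
      }
    }
    }

    // fold batch into running moments
    for (long v = 0; v < nvox; ++v) {
      sum[v] += t.batch[v];
      sumsq[v] += t.batch[v] * t.batch[v];
      t.batch[v] = 0.0;
    }

    if (use_target && b + 1 >= min_batches) {
      int B = b + 1;
      double mx = 0;
      for (long v = 0; v < nvox; ++v) if (sum[v] > mx) mx = sum[v];
      if (mx > 0) {
        double thr = dose_threshold_frac * mx, acc = 0; long n = 0;
        for (long v = 0; v < nvox; ++v) {
          if (sum[v] > thr) {
            double mean = sum[v] / B;
            double varb = (sumsq[v] / B - mean * mean) * B / (B - 1.0);
            if (varb < 0) varb = 0;
            acc += std::sqrt(varb / B) / mean;
            ++n;
          }
        }
        if (n > 0) {
          agg_unc = acc / n;
          if (agg_unc <= target_unc) { ++b; break; }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  int B = use_target ? std::min(b, max_batches) : n_batches;
  if (B < 1) B = 1;
  // map back from the z-fast internal layout to the x-fast R array layout
  NumericVector mean_dose(nvox), rel_unc(nvox);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long vr = (long)i + (long)g.nx * ((long)j + (long)g.ny * k);
        long vz = (long)k + (long)g.nz * ((long)i + (long)g.nx * j);
        double mean = sum[vz] / B;
        mean_dose[vr] = mean;
        if (B > 1 && mean > 0) {
          double varb = (sumsq[vz] / B - mean * mean) * B / (B - 1.0);
          if (varb < 0) varb = 0;
          rel_unc[vr] = std::sqrt(varb / B) / mean;
        } else rel_unc[vr] = NA_REAL;
      }
  // aggregate at final state
  double mx = 0;
  for (long v = 0; v < nvox; ++v) if (mean_dose[v] > mx) mx = mean_dose[v];
  double acc = 0; long nagg = 0;
  if (mx > 0) {
    double thr = dose_threshold_frac * mx;
    for (long v = 0; v < nvox; ++v)
      if (mean_dose[v] > thr && R_finite(rel_unc[v])) { acc += rel_unc[v]; ++nagg; }
  }
  double agg = nagg > 0 ? acc / nagg : NA_REAL;

  return List::create(
    _["tally_mean"] = mean_dose,      // water-equivalent MeV per batch per voxel
    _["rel_unc"] = rel_unc,
    _["n_batches"] = B,
    _["histories"] = (double)B * H,
    _["batch_hist"] = (double)H,
    _["aggregate_unc"] = agg,
    _["reached_target"] = use_target ? (agg <= target_unc) : true,
    _["injected_mev"] = t.injected,
    _["deposited_mev"] = t.deposited,
    _["escaped_mev"] = t.escaped,
    _["n_steps"] = (double)n_steps, _["n_bsteps"] = (double)n_bsteps);
}

// --- small sampling kernels shared with the R-level operation wrappers ----

// [[Rcpp::export]]
NumericMatrix mcs_sample_cpp(double energy, double step_wet, double cum_wet,
                             double x0_mm, double step_phys, int n,
                             double seed, List phys_list) {
  PqaPhysics ph; ph.build(phys_list);
  NumericMatrix out(n, 2);
  PqaRng rng;
  double var = 0;
  if (step_wet > 0) {
    var = ph.pv2(energy) * (ph.Gfun(cum_wet + step_wet) - ph.Gfun(cum_wet)) / step_wet
          * (step_phys / x0_mm);
    if (var < 0) var = 0;
  }
  double s = std::sqrt(var);
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    out(i, 0) = s * rng.norm();
    out(i, 1) = s * rng.norm();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector straggle_sample_cpp(double mean_loss, double step_mm, double rsp,
                                  double kinetic_energy, int n, double seed,
                                  List phys_list) {
  PqaPhysics ph; ph.build(phys_list);
  NumericVector out(n);
  PqaRng rng;
  double s = step_mm > 0 ? std::sqrt(ph.bohr_mev2_per_mm * rsp * step_mm) : 0.0;
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    double dE = mean_loss + s * rng.norm();
    if (dE < 0) dE = 0;
    if (dE > kinetic_energy) dE = kinetic_energy;
    out[i] = dE;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector nuclear_sample_cpp(double energy, double step_mm, double nuc_scale,
                                 int n, double seed, List phys_list) {
  PqaPhysics ph; ph.build(phys_list);
  LogicalVector out(n);
  PqaRng rng;
  double pint = 1.0 - std::exp(-ph.sigma_nuc(energy) * nuc_scale * step_mm);
  for (int i = 0; i < n; ++i) {
    rng.seed((uint64_t)seed, (uint64_t)i);
    out[i] = rng.unif() < pint;
  }
  return out;
}
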