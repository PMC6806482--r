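#ifndef PQA_PHYSICS_H
#define PQA_PHYSICS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>

// Tabulated proton physics built from a parameter list created on the R side
// (see proton_physics()). All engine kernels draw on the same tables so the
// analytical and Monte Carlo engines share one range-energy model.

struct PqaPhysics {
  double alpha_cm, p;        // Bragg-Kleeman R[cm] = alpha * E^p
  double es_mev;             // Highland constant (MeV)
  double x0_water_mm;        // water radiation length (mm)
  double bohr_mev2_per_mm;   // Bohr straggling variance rate in water
  double kappa;              // nuclear secondary forward-peaking parameter
  double cutoff_mev;         // transport cutoff
  double tail_emax;          // below this, residual range deposited as CSDA segment
  double frac_p, frac_d, frac_a, frac_neutral, frac_local;
  double ev_local_frac;      // d + alpha + heavy recoil share, tallied as expected value
  double mp;                 // proton rest mass (MeV)

  // tables
  double e_max, e_step, inv_e_step;
  std::vector<double> tab_S;      // stopping power water MeV/mm vs E
  std::vector<double> tab_pv2;    // (es/pv)^2 vs E
  std::vector<double> tab_sigma;  // nonelastic macroscopic cross section per mm (water) vs E
  double r_max, r_step, inv_r_step;
  std::vector<double> tab_EofR;   // E vs residual range (water mm)
  double g_max, g_step, inv_g_step;
  std::vector<double> tab_G;      // telescoped Highland profile G(t)
  std::vector<double> tab_RofE;   // CSDA range (water mm) vs E

  double range_mm(double E) const { return 10.0 * alpha_cm * std::pow(E, p); }
  double S_water_exact(double E) const {
    return std::pow(E, 1.0 - p) / (10.0 * alpha_cm * p);
  }

  inline double lin(const std::vector<double> &tab, double x, double inv_step,
                    double xmax) const {
    if (x <= 0) return tab[0];
    if (x >= xmax) return tab[tab.size() - 1];
    double f = x * inv_step;
    size_t i = (size_t)f;
    double w = f - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
  }

  inline double S_water(double E) const { return lin(tab_S, E, inv_e_step, e_max); }
  inline double pv2(double E) const { return lin(tab_pv2, E, inv_e_step, e_max); }
  inline double sigma_nuc(double E) const { return lin(tab_sigma, E, inv_e_step, e_max); }
  inline double E_of_R(double R) const {
    if (R <= 0) return 0.0;
    return lin(tab_EofR, R, inv_r_step, r_max);
  }
  inline double R_of_E(double E) const {
    if (E <= 0) return 0.0;
    return lin(tab_RofE, E, inv_e_step, e_max);
  }

  // Telescoped Highland profile: G(t) = t * (1 + log10(t/X0)/9)^2 with the
  // bracket clamped at zero; per-step angular variance is
  // pv2(E_mid) * (G(t + L_wet) - G(t)) / L_wet * (L_phys / X0_material).
  inline double Gfun_exact(double t) const {
    if (t <= 0) return 0.0;
    double b = 1.0 + std::log10(t / x0_water_mm) / 9.0;
    if (b < 0) b = 0.0;
    return t * b * b;
  }
  inline double Gfun(double t) const {
    if (t <= 0) return 0.0;
    if (t >= g_max) return lin(tab_G, g_max, inv_g_step, g_max) +
      (t - g_max); // asymptotically G' ~ 1 at large t
    return lin(tab_G, t, inv_g_step, g_max);
  }

  void build(const Rcpp::List &phys) {
    alpha_cm = Rcpp::as<double>(phys["alpha_cm"]);
    p = Rcpp::as<double>(phys["p"]);
    es_mev = Rcpp::as<double>(phys["es_mev"]);
    x0_water_mm = Rcpp::as<double>(phys["x0_water_mm"]);
    bohr_mev2_per_mm = Rcpp::as<double>(phys["bohr_mev2_per_mm"]);
    kappa = Rcpp::as<double>(phys["kappa"]);
    cutoff_mev = Rcpp::as<double>(phys["cutoff_mev"]);
    tail_emax = Rcpp::as<double>(phys["tail_emax"]);
    mp = 938.272;
    Rcpp::NumericVector fr = phys["energy_fractions"]; // p, d, a, neutral, local
    frac_p = fr[0]; frac_d = fr[1]; frac_a = fr[2];
    frac_neutral = fr[3]; frac_local = fr[4];
    ev_local_frac = frac_d + frac_a + frac_local;

    Rcpp::NumericVector nucE = phys["nuclear_e_mev"];
    Rcpp::NumericVector nucS = phys["nuclear_sigma_per_mm"];

    e_max = 300.0; e_step = 0.05;
    size_t ne = (size_t)(e_max / e_step) + 2;
    tab_S.resize(ne); tab_pv2.resize(ne); tab_sigma.resize(ne);
    for (size_t i = 0; i < ne; ++i) {
      double E = std::max(1e-3, i * e_step);
      tab_S[i] = S_water_exact(E);
      double Etot = E + mp;
      double pc2 = Etot * Etot - mp * mp;
      double pv = pc2 / Etot; // p*c*beta
      tab_pv2[i] = (es_mev / pv) * (es_mev / pv);
      // piecewise-linear nuclear cross section, zero below threshold
      double sg = 0.0;
      int na = nucE.size();
      if (E >= nucE[0]) {
        if (E >= nucE[na - 1]) sg = nucS[na - 1];
        else {
          for (int k = 0; k < na - 1; ++k) {
            if (E >= nucE[k] && E < nucE[k + 1]) {
              double w = (E - nucE[k]) / (nucE[k + 1] - nucE[k]);
              sg = nucS[k] * (1.0 - w) + nucS[k + 1] * w;
              break;
            }
          }
        }
      }
      tab_sigma[i] = sg;
    }
    inv_e_step = 1.0 / e_step;
    tab_RofE.resize(ne);
    for (size_t i = 0; i < ne; ++i) tab_RofE[i] = range_mm(std::max(1e-3, i * e_step));
    r_max = range_mm(e_max); r_step = 0.05;
    size_t nr = (size_t)(r_max / r_step) + 2;
    tab_EofR.resize(nr);
    for (size_t i = 0; i < nr; ++i) {
      double R = i * r_step;
      tab_EofR[i] = std::pow(R / (10.0 * alpha_cm), 1.0 / p);
    }
    inv_r_step = 1.0 / r_step;
    g_max = 700.0; g_step = 0.25;
    size_t ng = (size_t)(g_max / g_step) + 2;
    tab_G.resize(ng);
    for (size_t i = 0; i < ng; ++i) tab_G[i] = Gfun_exact(i * g_step);
    inv_g_step = 1.0 / g_step;
  }
};

#endif
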