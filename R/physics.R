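#' Proton physics parameter set
#'
#' Bundles the physical model constants shared by both dose engines: the
#' Bragg-Kleeman range-energy relation \eqn{R = \alpha E^p}, the Highland
#' multiple-Coulomb-scattering parameterization, Bohr energy-loss straggling,
#' a piecewise-linear macroscopic nonelastic nuclear cross section in water,
#' and the fixed partition of the energy released in a nonelastic interaction
#' (secondary proton, deuteron, alpha, neutrals, heavy recoils).
#'
#' @param alpha_cm Bragg-Kleeman coefficient (cm MeV^-p); default 0.0022.
#' @param p Bragg-Kleeman exponent; default 1.77.
#' @param es_mev Highland constant (MeV); default 14.1.
#' @param x0_water_mm radiation length of water (mm); default 360.8.
#' @param bohr_mev2_per_mm Bohr straggling variance rate in water
#'   (MeV^2/mm); default 0.0087, which yields a stopping-depth spread of
#'   about 1.1% of range for therapeutic protons.
#' @param nuclear_e_mev,nuclear_sigma_per_mm anchors of the piecewise-linear
#'   macroscopic nonelastic cross section in water (per mm); zero below the
#'   first anchor (threshold, default 8 MeV).
#' @param energy_fractions named fractions of the interaction energy handed
#'   to secondary protons, deuterons, alphas, neutrals (removed from the
#'   simulation), and locally deposited heavy recoils; must sum to 1.
#' @param kappa forward-peaking parameter of the nuclear secondary emission
#'   angle (density proportional to exp(kappa cos theta)).
#' @param cutoff_mev transport cutoff; residual energy is deposited locally.
#' @param tail_emax below this energy the residual range (under 2 mm) is
#'   deposited as a straight CSDA segment.
#' @param protons_per_mu number of protons delivered per monitor unit; fixes
#'   the absolute dose calibration shared by both engines.
#' @return An object of class `proton_physics` (a named list).
#' @export
proton_physics <- function(alpha_cm = 0.0022, p = 1.77, es_mev = 14.1,
                           x0_water_mm = 360.8, bohr_mev2_per_mm = 0.0087,
                           nuclear_e_mev = c(8, 20, 50, 100, 150, 230),
                           nuclear_sigma_per_mm = c(0, 4e-4, 1.0e-3, 1.23e-3,
                                                    1.19e-3, 1.06e-3),
                           energy_fractions = c(p = 0.55, d = 0.05, a = 0.05,
                                                neutral = 0.25, local = 0.10),
                           kappa = 10, cutoff_mev = 1, tail_emax = 10,
                           protons_per_mu = 1e9) {
  stopifnot(alpha_cm > 0, p > 1, length(nuclear_e_mev) == length(nuclear_sigma_per_mm),
            all(diff(nuclear_e_mev) > 0), all(nuclear_sigma_per_mm >= 0))
  if (abs(sum(energy_fractions) - 1) > 1e-9)
    stop("energy_fractions must sum to 1")
  structure(list(alpha_cm = alpha_cm, p = p, es_mev = es_mev,
                 x0_water_mm = x0_water_mm,
                 bohr_mev2_per_mm = bohr_mev2_per_mm,
                 nuclear_e_mev = nuclear_e_mev,
                 nuclear_sigma_per_mm = nuclear_sigma_per_mm,
                 energy_fractions = unname(energy_fractions),
                 kappa = kappa, cutoff_mev = cutoff_mev, tail_emax = tail_emax,
                 protons_per_mu = protons_per_mu),
            class = "proton_physics")
}

default_physics <- function() {
  if (is.null(.pqa_env$physics)) .pqa_env$physics <- proton_physics()
  .pqa_env$physics
}

#' CSDA range of a proton in water
#'
#' Bragg-Kleeman power law `R[mm] = 10 alpha E^p`.
#'
#' @param energy kinetic energy (MeV), vectorized.
#' @param physics a [proton_physics()] object.
#' @return range in mm of water.
#' @export
proton_range <- function(energy, physics = default_physics()) {
  10 * physics$alpha_cm * energy^physics$p
}

#' Proton energy from residual CSDA range in water
#' @param range_mm residual range (mm water), vectorized.
#' @param physics a [proton_physics()] object.
#' @return kinetic energy (MeV).
#' @export
proton_energy_from_range <- function(range_mm, physics = default_physics()) {
  pmax(0, range_mm / (10 * physics$alpha_cm))^(1 / physics$p)
}

#' Mass stopping power model
#'
#' Differentiating the Bragg-Kleeman range-energy relation gives the
#' parameterized Bethe-Bloch stand-in `S(E) = E^(1-p) / (10 alpha p)` in
#' water; other materials scale by their relative stopping power.
#'
#' @param energy kinetic energy MeV (vectorized).
#' @param material a material spec (see [material_spec()]); default water.
#' @param physics a [proton_physics()] object.
#' @return stopping power in MeV/mm.
#' @export
stopping_power <- function(energy, material = NULL, physics = default_physics()) {
  if (any(energy <= 0)) stop("energy must be positive")
  rsp <- if (is.null(material)) 1 else material$rsp
  energy^(1 - physics$p) / (10 * physics$alpha_cm * physics$p) * rsp
}

# (es / pv)^2 with pv = p*c*beta for a proton of kinetic energy E
pv_factor2 <- function(energy, physics = default_physics()) {
  mp <- 938.272
  etot <- energy + mp
  pv <- (etot^2 - mp^2) / etot
  (physics$es_mev / pv)^2
}

# Telescoped Highland profile G(t) = t (1 + log10(t/X0)/9)^2, bracket clamped
highland_G <- function(t, physics = default_physics()) {
  b <- pmax(0, 1 + log10(pmax(t, 1e-12) / physics$x0_water_mm) / 9)
  ifelse(t <= 0, 0, t * b^2)
}

#' Highland multiple-scattering sigma for one step
#'
#' Projected-angle standard deviation for a step of water-equivalent
#' thickness `step_wet` taken after `cum_wet` of material has already been
#' traversed. The Highland logarithmic correction is evaluated on the
#' cumulative thickness (telescoped form), so angular variance is additive
#' over sub-steps and a single step from zero reproduces the classic
#' Highland formula.
#'
#' @param energy kinetic energy (MeV).
#' @param step_wet step water-equivalent thickness (mm).
#' @param cum_wet cumulative water-equivalent thickness already traversed (mm).
#' @param x0_mm radiation length of the medium (mm); default water.
#' @param step_phys physical step length (mm); defaults to `step_wet`.
#' @param physics a [proton_physics()] object.
#' @return projected-angle sigma (radians).
#' @export
highland_sigma <- function(energy, step_wet, cum_wet = 0, x0_mm = NULL,
                           step_phys = NULL, physics = default_physics()) {
  if (step_wet <= 0) return(0)
  if (is.null(x0_mm)) x0_mm <- physics$x0_water_mm
  if (is.null(step_phys)) step_phys <- step_wet
  dG <- highland_G(cum_wet + step_wet, physics) - highland_G(cum_wet, physics)
  sqrt(pmax(0, pv_factor2(energy, physics) * dG / step_wet * step_phys / x0_mm))
}

# macroscopic nonelastic cross section in water (per mm), piecewise linear
nuclear_sigma <- function(energy, physics = default_physics()) {
  e <- physics$nuclear_e_mev
  s <- physics$nuclear_sigma_per_mm
  out <- approx(e, s, xout = pmin(pmax(energy, e[1]), e[length(e)]),
                rule = 2)$y
  out[energy < e[1]] <- 0
  out
}

# physics list in the form the C++ kernels expect
physics_for_cpp <- function(physics = default_physics()) {
  list(alpha_cm = physics$alpha_cm, p = physics$p, es_mev = physics$es_mev,
       x0_water_mm = physics$x0_water_mm,
       bohr_mev2_per_mm = physics$bohr_mev2_per_mm,
       kappa = physics$kappa, cutoff_mev = physics$cutoff_mev,
       tail_emax = physics$tail_emax,
       energy_fractions = physics$energy_fractions,
       nuclear_e_mev = physics$nuclear_e_mev,
       nuclear_sigma_per_mm = physics$nuclear_sigma_per_mm)
}

#' Sample multiple-Coulomb-scattering deflections
#'
#' Draws Gaussian projected-angle deflection pairs for a condensed-history
#' step, using the same Highland kernel as the transport engine. The
#' deflection is zero for a zero-thickness step.
#'
#' @inheritParams highland_sigma
#' @param n number of samples.
#' @param seed RNG seed (engine-internal counter-based streams).
#' @return matrix with columns `theta_x`, `theta_y` (radians).
#' @export
sample_scattering_angle <- function(energy, step_wet, cum_wet = 0,
                                    x0_mm = NULL, step_phys = NULL, n = 1,
                                    seed = 1, physics = default_physics()) {
  stopifnot(step_wet >= 0)
  if (is.null(x0_mm)) x0_mm <- physics$x0_water_mm
  if (is.null(step_phys)) step_phys <- step_wet
  m <- mcs_sample_cpp(energy, step_wet, cum_wet, x0_mm, step_phys, as.integer(n),
                      seed, physics_for_cpp(physics))
  colnames(m) <- c("theta_x", "theta_y")
  m
}

#' Sample straggled energy loss for a step
#'
#' Gaussian (Bohr) energy-loss straggling about the mean loss, truncated to
#' the physical interval `[0, kinetic_energy]`.
#'
#' @param mean_loss mean energy loss over the step (MeV).
#' @param step_mm physical step length (mm).
#' @param rsp relative stopping power of the medium (scales the Bohr
#'   variance rate, a proxy for relative electron density).
#' @param kinetic_energy current kinetic energy (MeV), the upper truncation.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param physics a [proton_physics()] object.
#' @return sampled energy losses (MeV).
#' @export
sample_energy_straggling <- function(mean_loss, step_mm, rsp = 1,
                                     kinetic_energy = Inf, n = 1, seed = 1,
                                     physics = default_physics()) {
  stopifnot(mean_loss >= 0, step_mm >= 0)
  straggle_sample_cpp(mean_loss, step_mm, rsp, kinetic_energy, as.integer(n),
                      seed, physics_for_cpp(physics))
}

#' Sample occurrence of a nonelastic nuclear interaction
#'
#' Bernoulli draw with probability `1 - exp(-Sigma(E) * scale * step)`, with
#' the tabulated macroscopic cross section; zero below the threshold energy.
#'
#' @param energy proton kinetic energy (MeV).
#' @param step_mm step length (mm).
#' @param nuclear_scale material multiplier on the water cross section.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param physics a [proton_physics()] object.
#' @return logical vector; `TRUE` where an interaction occurred.
#' @export
sample_nuclear_interaction <- function(energy, step_mm, nuclear_scale = 1,
                                       n = 1, seed = 1,
                                       physics = default_physics()) {
  nuclear_sample_cpp(energy, step_mm, nuclear_scale, as.integer(n), seed,
                     physics_for_cpp(physics))
}

# run code with a private RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
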