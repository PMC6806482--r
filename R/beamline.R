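#' PBS beamline configuration
#'
#' Captures the delivery geometry and calibration shared by both engines:
#' the upstream range shifter (modeled purely as water-equivalent
#' thickness), the air gap to the phantom, the in-air spot size model, the
#' machine energy list and the monitor-unit calibration.
#'
#' @param range_shifter_wet range shifter water-equivalent thickness (mm);
#'   0 for an open beamline, 75 for the shallow-target configuration.
#' @param air_gap air gap between range shifter and phantom surface (mm).
#' @param available_energies machine energy list (MeV), strictly increasing.
#' @param sigma_air_params in-air spot sigma at the phantom surface:
#'   `sigma0(E) = a + b (E - eref)` mm.
#' @param sigma_growth_per_mm_airgap additional sigma per mm of air gap
#'   (mm/mm), representing divergence picked up in the shifter.
#' @param protons_per_mu protons delivered per monitor unit (the absolute
#'   calibration; see [proton_physics()]).
#' @return object of class `beamline_config`.
#' @export
beamline_config <- function(range_shifter_wet = 0, air_gap = 20,
                            available_energies = seq(70, 230, by = 0.5),
                            sigma_air_params = c(a = 8, b = -0.025, eref = 70),
                            sigma_growth_per_mm_airgap = 0.05,
                            protons_per_mu = 1e9) {
  stopifnot(range_shifter_wet >= 0, air_gap >= 0,
            all(diff(available_energies) > 0))
  structure(list(range_shifter_wet = range_shifter_wet, air_gap = air_gap,
                 available_energies = available_energies,
                 sigma_air_params = sigma_air_params,
                 sigma_growth_per_mm_airgap = sigma_growth_per_mm_airgap,
                 protons_per_mu = protons_per_mu),
            class = "beamline_config")
}

#' In-air spot sigma at the phantom surface
#'
#' Linear-in-energy nozzle model plus air-gap growth when a range shifter
#' is present (the shifter is the dominant source of in-air divergence).
#'
#' @param beamline a [beamline_config()].
#' @param energy MeV (vectorized).
#' @return sigma in mm.
#' @export
spot_sigma_air <- function(beamline, energy) {
  p <- beamline$sigma_air_params
  s <- p[["a"]] + p[["b"]] * (energy - p[["eref"]])
  if (beamline$range_shifter_wet > 0)
    s <- s + beamline$sigma_growth_per_mm_airgap * beamline$air_gap
  pmax(s, 1)
}

# snap to the machine energy list; error outside range naming the nearest
snap_energy <- function(beamline, energy) {
  av <- beamline$available_energies
  if (energy < min(av) - 1e-9 || energy > max(av) + 1e-9)
    stop(sprintf("energy %.1f MeV outside machine list; nearest available is %.1f MeV",
                 energy, av[which.min(abs(av - energy))]))
  av[which.min(abs(av - energy))]
}
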