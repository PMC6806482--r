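#' Condensed-history Monte Carlo proton transport
#'
#' Runs the Class II transport engine on the phantom grid: primaries are
#' sampled from the plan's weighted spot list, stepped with exact
#' Bragg-Kleeman mean energy loss, Bohr straggling, Highland multiple
#' scattering (midpoint hinge) and table-driven nonelastic nuclear
#' interactions; dose is tallied as dose-to-water with batch statistics.
#' The run stops either after a fixed number of histories or at the first
#' batch where the mean relative uncertainty over voxels above 50% of the
#' maximum dose reaches the target (default 0.5%).
#'
#' @param plan a [pbs_plan()] (single +z beam).
#' @param phantom a [voxel_phantom()].
#' @param grid_spacing dose grid spacing (mm); default the phantom grid.
#' @param stop stopping rule: `list(histories = N)` or
#'   `list(uncertainty = u)` (relative, e.g. 0.005).
#' @param seed master RNG seed; per-history streams are derived from it,
#'   so results are reproducible.
#' @param beam beam index.
#' @param batch_hist histories per batch (default: histories/20 in
#'   fixed-history mode, 50000 in uncertainty mode).
#' @param n_batches number of batches in fixed-history mode (default 20).
#' @param max_batches cap for uncertainty mode.
#' @param open_step_mm step cap inside homogeneous regions (mm).
#' @param range_step_frac near-peak step cap as a fraction of the residual
#'   range (resolves the Bragg peak; smaller is finer).
#' @param dose_threshold_frac dose fraction defining the uncertainty
#'   aggregation region (default 0.5).
#' @param physics a [proton_physics()] object.
#' @return a [dose_cube()] (engine `"mc"`) whose `meta$run_stats` holds the
#'   batch count, histories, aggregate uncertainty, the energy-conservation
#'   ledger (injected, deposited and escaped MeV) and the seed.
#' @export
mc_transport <- function(plan, phantom, grid_spacing = NULL,
                         stop = list(uncertainty = 0.005), seed = 1,
                         beam = 1, batch_hist = NULL, n_batches = 20,
                         max_batches = 10000, open_step_mm = 6,
                         range_step_frac = 0.2, dose_threshold_frac = 0.5,
                         physics = default_physics()) {
  b <- plan$beams[[beam]]
  if (max(abs(b$direction - c(0, 0, 1))) > 1e-9)
    stop("engine transports along +z; rotate the phantom into beam-eye-view")
  ph <- if (is.null(grid_spacing)) phantom else resample_phantom(phantom, grid_spacing)
  sm <- plan_spot_matrix(plan, beam)
  if (sum(sm[, "weight"]) <= 0) stop("plan has zero total weight")
  mv <- material_vectors(ph$materials)

  target_unc <- -1; nb <- n_batches
  if (!is.null(stop$uncertainty)) {
    target_unc <- stop$uncertainty
    if (is.null(batch_hist)) batch_hist <- 50000L
  } else if (!is.null(stop$histories)) {
    if (is.null(batch_hist)) batch_hist <- max(1L, as.integer(ceiling(stop$histories / n_batches)))
    nb <- max(1L, as.integer(round(stop$histories / batch_hist)))
  } else stop("stop must name histories or uncertainty")

  res <- mc_transport_cpp(ph$material_index - 1L, as.integer(ph$dims),
                          ph$spacing, ph$origin, mv$rsp, mv$x0_mm, mv$nuc,
                          cbind(sm[, "x"], sm[, "y"], sm[, "energy"],
                                sm[, "weight"], sm[, "sigma_air"]),
                          b$beamline$range_shifter_wet,
                          physics_for_cpp(physics), open_step_mm, open_step_mm, range_step_frac,
                          as.integer(batch_hist), as.integer(nb), target_unc,
                          10L, as.integer(max_batches), seed,
                          dose_threshold_frac)

  # tally_mean is water-equivalent MeV per batch per voxel; one batch
  # carries batch_hist histories, and the whole plan delivers
  # total_MU * protons_per_mu protons
  vol <- prod(ph$spacing)
  scale <- plan_total_mu(plan) * b$beamline$protons_per_mu / res$batch_hist *
    1.602e-7 / vol
  dose <- array(res$tally_mean, ph$dims) * scale
  stats <- list(n_batches = res$n_batches, histories = res$histories,
                aggregate_unc = res$aggregate_unc,
                reached_target = res$reached_target,
                injected_mev = res$injected_mev,
                deposited_mev = res$deposited_mev,
                escaped_mev = res$escaped_mev, seed = seed,
                target_unc = if (target_unc > 0) target_unc else NA_real_)
  if (target_unc > 0 && !isTRUE(res$reached_target))
    warning("uncertainty target not reached within max_batches; partial result flagged")
  dose_cube(dose, ph$spacing, ph$origin, engine = "mc",
            rel_unc = array(res$rel_unc, ph$dims),
            meta = list(plan = plan$label, run_stats = stats))
}

#' Monte Carlo run statistics
#'
#' @param cube an MC [dose_cube()].
#' @return the `run_stats` list (batches, histories, aggregate uncertainty
#'   over the >50%-of-max region, energy ledger, seed).
#' @export
run_stats <- function(cube) {
  rs <- cube$meta$run_stats
  if (is.null(rs)) stop("not a Monte Carlo dose cube")
  rs
}

#' Write run statistics to a JSON sidecar
#' @param cube an MC [dose_cube()].
#' @param path output path.
#' @export
write_run_stats <- function(cube, path) {
  writeLines(jsonlite::toJSON(run_stats(cube), digits = NA, auto_unbox = TRUE),
             path)
  invisible(path)
}
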