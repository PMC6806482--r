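#' Dose cube container
#'
#' 3D absolute dose (Gy) on a regular grid aligned with the phantom, plus a
#' per-voxel relative-uncertainty companion for Monte Carlo results.
#'
#' @param dose 3D array (Gy).
#' @param spacing mm per axis (length 3).
#' @param origin center of voxel `[1,1,1]` (mm).
#' @param engine `"apb"` or `"mc"`.
#' @param rel_unc optional relative-uncertainty array (MC).
#' @param meta optional named list (plan label, run stats, ...).
#' @return object of class `dose_cube`.
#' @export
dose_cube <- function(dose, spacing, origin, engine = c("apb", "mc"),
                      rel_unc = NULL, meta = list()) {
  engine <- match.arg(engine)
  stopifnot(length(dim(dose)) == 3, all(spacing > 0), length(origin) == 3)
  if (any(dose < 0)) stop("dose must be nonnegative")
  structure(list(dose = dose, dims = dim(dose), spacing = as.numeric(spacing),
                 origin = as.numeric(origin), engine = engine,
                 rel_unc = rel_unc, meta = meta),
            class = "dose_cube")
}

#' @export
print.dose_cube <- function(x, ...) {
  cat(sprintf("dose cube [%s]: %d x %d x %d @ %s mm, max %.4g Gy\n",
              x$engine, x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 3), collapse = "x"), max(x$dose)))
  if (!is.null(x$meta$run_stats))
    cat(sprintf("  MC: %d batches, %.3g histories, aggregate uncertainty %.2f%%\n",
                x$meta$run_stats$n_batches, x$meta$run_stats$histories,
                100 * x$meta$run_stats$aggregate_unc))
  invisible(x)
}

# voxel-center axes of a cube
cube_axes <- function(cube) {
  lapply(1:3, function(a) cube$origin[a] + (seq_len(cube$dims[a]) - 1) * cube$spacing[a])
}

cube_z_front <- function(cube) cube$origin[3] - cube$spacing[3] / 2

#' Fermi-Eyges lateral sigma profile of a pencil beam
#'
#' Accumulates the Highland per-step angular variance along the beam axis
#' and propagates it to lateral position spread at each depth,
#' `sigma_mcs^2(z) = sum_i dvar_i (z - z_i)^2`, added in quadrature to the
#' in-air spot sigma. The Highland logarithmic factor is evaluated on
#' cumulative water-equivalent thickness, matching the Monte Carlo engine.
#'
#' @param energy nozzle energy (MeV).
#' @param z physical depth grid (mm, increasing, roughly uniform); defaults
#'   to `wed` (water).
#' @param wed cumulative water-equivalent depth at `z` (mm).
#' @param rsp,x0_mm relative stopping power and radiation length (mm) along
#'   the column (scalar or per-z vector).
#' @param rs_wet upstream range-shifter WET (mm).
#' @param sigma0 in-air sigma at the surface (mm).
#' @param physics a [proton_physics()] object.
#' @return total sigma (mm) at each `z`.
#' @export
fe_sigma_profile <- function(energy, z = NULL, wed, rsp = 1, x0_mm = NULL,
                             rs_wet = 0, sigma0 = 0,
                             physics = default_physics()) {
  if (is.null(z)) z <- wed
  if (is.null(x0_mm)) x0_mm <- physics$x0_water_mm
  n <- length(z)
  if (length(rsp) == 1) rsp <- rep(rsp, n)
  if (length(x0_mm) == 1) x0_mm <- rep(x0_mm, n)
  R0 <- proton_range(energy, physics)
  dz <- diff(z)
  wmid <- (wed[-1] + wed[-n]) / 2
  lwet <- pmax(diff(wed), 1e-9)
  eres <- R0 - rs_wet - wmid
  Emid <- proton_energy_from_range(pmax(eres, 0.5), physics)
  dG <- highland_G(rs_wet + wed[-1], physics) - highland_G(rs_wet + wed[-n], physics)
  dvar <- pv_factor2(Emid, physics) * dG / lwet * dz / x0_mm[-n]
  dvar[eres <= 0.5] <- 0
  zmid <- (z[-1] + z[-n]) / 2
  c0 <- cumsum(dvar); c1 <- cumsum(dvar * zmid); c2 <- cumsum(dvar * zmid^2)
  sig2 <- c(0, z[-1]^2 * c0 - 2 * z[-1] * c1 + c2)
  sqrt(sigma0^2 + pmax(sig2, 0))
}

#' Analytical pencil-beam dose calculation
#'
#' For every spot the water-equivalent depth is computed along the spot's
#' central axis only (the infinite-slab approximation), the depth dose is
#' the energy's IDD evaluated at that WED (plus the range-shifter WET), and
#' the lateral term is a normalized 2D Gaussian whose sigma follows the
#' Fermi-Eyges accumulation of Highland scattering along the axis. The
#' engine is deliberately blind to heterogeneity that does not intersect a
#' spot's axis.
#'
#' @param plan a [pbs_plan()] (single +z beam; see [rotate_phantom()] for
#'   oblique incidence).
#' @param phantom a [voxel_phantom()].
#' @param grid_spacing dose grid spacing (mm); default the phantom grid.
#' @param beam beam index.
#' @param trunc_nsigma lateral Gaussian truncation radius in sigmas.
#' @param subspots split every spot into an `subspots x subspots` bundle of
#'   closely spaced mini-beams, each raytracing its own axis (finer lateral
#'   sampling of heterogeneity; 1 = one pencil per spot).
#' @param halo_fraction optional nuclear-halo term: this fraction of each
#'   spot's fluence is carried by a broad Gaussian of `halo_sigma_mm`
#'   (default off; the vendor's halo model is proprietary).
#' @param halo_sigma_mm halo Gaussian sigma (mm).
#' @param physics a [proton_physics()] object.
#' @return a [dose_cube()] (engine `"apb"`).
#' @export
compute_dose_apb <- function(plan, phantom, grid_spacing = NULL, beam = 1,
                             trunc_nsigma = 4, subspots = 1,
                             halo_fraction = 0, halo_sigma_mm = 15,
                             physics = default_physics()) {
  b <- plan$beams[[beam]]
  if (max(abs(b$direction - c(0, 0, 1))) > 1e-9)
    stop("engine transports along +z; rotate the phantom into beam-eye-view")
  ph <- if (is.null(grid_spacing)) phantom else resample_phantom(phantom, grid_spacing)
  rs <- b$beamline$range_shifter_wet
  sm <- plan_spot_matrix(plan, beam)
  if (subspots > 1) sm <- split_subspots(sm, as.integer(subspots))
  zc <- phantom_axes(ph)[[3]]
  nz <- length(zc)
  mv <- material_vectors(ph$materials)

  # group spots by (energy, axis column): shared depth profile
  lo <- ph$origin - ph$spacing / 2
  ix <- pmin(pmax(floor((sm[, "x"] - lo[1]) / ph$spacing[1]), 0), ph$dims[1] - 1)
  iy <- pmin(pmax(floor((sm[, "y"] - lo[2]) / ph$spacing[2]), 0), ph$dims[2] - 1)
  gkey <- paste(sm[, "energy"], ix, iy)
  groups <- unique(gkey)
  gid <- match(gkey, groups)

  idd_m <- matrix(0, nz, length(groups))
  sig_m <- matrix(1, nz, length(groups))
  for (gi in seq_along(groups)) {
    s <- which(gid == gi)[1]
    E <- sm[s, "energy"]
    curve <- bragg_idd(E, beamline = b$beamline, physics = physics)
    wed_z <- wed_column(ph, sm[s, "x"], sm[s, "y"], zc)
    if (any(is.na(wed_z))) { idd_m[, gi] <- 0; next } # axis misses the grid
    col_k <- pmin(pmax(floor((zc - lo[3]) / ph$spacing[3]), 0), ph$dims[3] - 1) + 1
    mat_col <- ph$material_index[ix[s] + 1, iy[s] + 1, col_k]
    idd_m[, gi] <- idd_value(curve, rs + wed_z)
    sig_m[, gi] <- fe_sigma_profile(E, z = zc, wed = wed_z,
                                    rsp = mv$rsp[mat_col],
                                    x0_mm = mv$x0_mm[mat_col], rs_wet = rs,
                                    sigma0 = sm[s, "sigma_air"],
                                    physics = physics)
  }

  spots_cpp <- cbind(sm[, "x"], sm[, "y"], sm[, "weight"] * (1 - halo_fraction),
                     gid)
  d <- apb_deposit_cpp(as.integer(ph$dims), ph$spacing, ph$origin, spots_cpp,
                       idd_m, sig_m, trunc_nsigma)
  if (halo_fraction > 0) {
    sig_h <- sqrt(sig_m^2 + halo_sigma_mm^2)
    spots_h <- cbind(sm[, "x"], sm[, "y"], sm[, "weight"] * halo_fraction, gid)
    d <- d + apb_deposit_cpp(as.integer(ph$dims), ph$spacing, ph$origin,
                             spots_h, idd_m, sig_h, trunc_nsigma)
  }
  dose_cube(array(d, ph$dims), ph$spacing, ph$origin, engine = "apb",
            meta = list(plan = plan$label))
}

# split each spot into an n x n bundle of mini-beams on a sigma-spaced
# lattice; the Gaussian-weighted bundle reproduces the spot's first and
# second lateral moments
split_subspots <- function(sm, n) {
  off <- (seq_len(n) - (n + 1) / 2)
  out <- vector("list", nrow(sm))
  for (s in seq_len(nrow(sm))) {
    sig <- sm[s, "sigma_air"]
    ctr <- expand.grid(dx = off * sig, dy = off * sig)
    w <- dnorm(ctr$dx, 0, sig) * dnorm(ctr$dy, 0, sig)
    w <- w / sum(w)
    vlat <- sum(w * ctr$dx^2) - sum(w * ctr$dx)^2
    sig_s <- sqrt(max(sig^2 - vlat, (0.3 * sig)^2))
    out[[s]] <- cbind(x = sm[s, "x"] + ctr$dx, y = sm[s, "y"] + ctr$dy,
                      energy = sm[s, "energy"], weight = sm[s, "weight"] * w,
                      sigma_air = sig_s)
  }
  do.call(rbind, out)
}

#' Central-axis APB depth-dose profile
#'
#' Fast analytic evaluation of the APB dose along a +z line (all spots'
#' Gaussians summed at the line), used for SOBP verification without
#' computing a full cube.
#'
#' @param plan a [pbs_plan()].
#' @param phantom a [voxel_phantom()], or NULL for semi-infinite water.
#' @param x,y lateral position of the line (mm).
#' @param z depth grid (mm); default 1-mm steps over the plan's range.
#' @param beam beam index.
#' @param physics a [proton_physics()] object.
#' @return data frame with `z` and `dose` (Gy).
#' @export
apb_axis_profile <- function(plan, phantom = NULL, x = 0, y = 0, z = NULL,
                             beam = 1, physics = default_physics()) {
  b <- plan$beams[[beam]]
  rs <- b$beamline$range_shifter_wet
  energies <- vapply(b$layers, function(l) l$energy, 0)
  if (is.null(z)) {
    zmax <- max(proton_range(energies, physics)) - rs + 30
    z <- seq(0.5, max(zmax, 10), by = 1)
  }
  if (is.null(phantom)) {
    wed_z <- z
    rsp_col <- 1; x0_col <- physics$x0_water_mm
  } else {
    wed_z <- wed_column(phantom, x, y, z)
    lo3 <- phantom$origin[3] - phantom$spacing[3] / 2
    kk <- pmin(pmax(floor((z - lo3) / phantom$spacing[3]), 0), phantom$dims[3] - 1) + 1
    lo <- phantom$origin - phantom$spacing / 2
    i <- pmin(pmax(floor((x - lo[1]) / phantom$spacing[1]), 0), phantom$dims[1] - 1) + 1
    j <- pmin(pmax(floor((y - lo[2]) / phantom$spacing[2]), 0), phantom$dims[2] - 1) + 1
    mv <- material_vectors(phantom$materials)
    mat_col <- phantom$material_index[i, j, kk]
    rsp_col <- mv$rsp[mat_col]; x0_col <- mv$x0_mm[mat_col]
  }
  dose <- numeric(length(z))
  for (l in b$layers) {
    curve <- bragg_idd(l$energy, beamline = b$beamline, physics = physics)
    sig0 <- spot_sigma_air(b$beamline, l$energy)
    sigz <- fe_sigma_profile(l$energy, z = z, wed = wed_z, rsp = rsp_col,
                             x0_mm = x0_col, rs_wet = rs, sigma0 = sig0,
                             physics = physics)
    iddz <- idd_value(curve, rs + wed_z)
    d2 <- outer(rep(x, length(z)), l$spots$x, "-")^2 +
      outer(rep(y, length(z)), l$spots$y, "-")^2
    g <- exp(-d2 / (2 * sigz^2)) %*% l$spots$weight
    dose <- dose + iddz * as.numeric(g) / (2 * pi * sigz^2)
  }
  data.frame(z = z, dose = dose)
}
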