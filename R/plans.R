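#' PBS plan container
#'
#' A plan is a list of beams; each beam carries a unit gantry direction (the
#' engines transport along +z; other directions are realized by rotating
#' the phantom into beam-eye-view), a [beamline_config()], and energy
#' layers holding weighted spots at the isocenter plane.
#'
#' @param beams list of beams, each `list(direction, beamline, layers)`
#'   where `layers` is a list of `list(energy, spots)` with `spots` a data
#'   frame of `x`, `y` (mm) and `weight` (MU).
#' @param label plan label (e.g. "F1").
#' @return object of class `pbs_plan`.
#' @export
pbs_plan <- function(beams, label = "plan") {
  stopifnot(length(beams) >= 1)
  for (b in beams) {
    stopifnot(length(b$direction) == 3, inherits(b$beamline, "beamline_config"),
              length(b$layers) >= 1)
    for (l in b$layers) {
      if (nrow(l$spots) == 0) stop("plan construction left an empty layer")
      if (any(l$spots$weight < 0)) stop("spot weights must be nonnegative")
    }
  }
  structure(list(beams = beams, label = label), class = "pbs_plan")
}

#' @export
print.pbs_plan <- function(x, ...) {
  ns <- n_spots(x)
  nl <- sum(vapply(x$beams, function(b) length(b$layers), 0L))
  cat(sprintf("PBS plan '%s': %d beam(s), %d energy layer(s), %d spots, %.3g MU\n",
              x$label, length(x$beams), nl, ns, plan_total_mu(x)))
  invisible(x)
}

#' Count spots in a plan
#' @param plan a [pbs_plan()].
#' @return integer.
#' @export
n_spots <- function(plan) {
  sum(vapply(plan$beams, function(b)
    sum(vapply(b$layers, function(l) nrow(l$spots), 0L)), 0L))
}

#' Total monitor units in a plan
#' @param plan a [pbs_plan()].
#' @return numeric (MU).
#' @export
plan_total_mu <- function(plan) {
  sum(vapply(plan$beams, function(b)
    sum(vapply(b$layers, function(l) sum(l$spots$weight), 0)), 0))
}

# flat spot matrix (x, y, energy, weight, sigma_air) for one beam
plan_spot_matrix <- function(plan, beam = 1) {
  b <- plan$beams[[beam]]
  rows <- lapply(b$layers, function(l)
    cbind(l$spots$x, l$spots$y, l$energy, l$spots$weight,
          spot_sigma_air(b$beamline, l$energy)))
  m <- do.call(rbind, rows)
  colnames(m) <- c("x", "y", "energy", "weight", "sigma_air")
  m
}

# 1D lateral weight profile: nonnegative weights making a Gaussian lattice
# flat over [lo, hi] (boosts edge spots so compact margins stay uniform)
lateral_weights_1d <- function(pos, sigma, lo, hi) {
  if (length(pos) == 1) return(1)
  pts <- seq(lo, hi, length.out = max(9, 3 * length(pos)))
  A <- exp(-outer(pts, pos, "-")^2 / (2 * sigma^2))
  w <- pracma::lsqnonneg(A, rep(1, length(pts)))$x
  if (all(w == 0)) rep(1, length(pos)) else w / max(w)
}

# spot lattice for one layer: spacing frac*sigma, symmetric about center
layer_lattice <- function(xlim, ylim, sigma, frac = 0.85, margin_sigma = 1.2) {
  half_x <- diff(xlim) / 2 + margin_sigma * sigma
  half_y <- diff(ylim) / 2 + margin_sigma * sigma
  a <- frac * sigma
  nx <- max(0, ceiling(half_x / a))
  ny <- max(0, ceiling(half_y / a))
  list(x = mean(xlim) + a * (-nx:nx), y = mean(ylim) + a * (-ny:ny), spacing = a)
}

#' Optimize a spread-out Bragg peak in water
#'
#' Builds the reference-beam style SOBP: pristine-peak layers spanning the
#' modulation, per-layer weights fit by nonnegative least squares against a
#' flat plateau objective on the central axis, a lateral spot lattice with
#' edge-enhanced weights, and a one-step range calibration so the distal
#' 90% point lands on the requested range.
#'
#' @param target_range_mm distal 90% depth in water (mm).
#' @param modulation_mm SOBP modulation width (mm).
#' @param prescription_gy plateau dose (Gy).
#' @param beamline a [beamline_config()].
#' @param field_mm lateral field size (x, y) in mm.
#' @param layer_spacing_mm spacing of layer ranges (mm).
#' @param spot_spacing_frac lattice spacing as a fraction of the in-air
#'   spot sigma.
#' @param plateau_trim plateau evaluation margin inside the nominal
#'   modulation interval (mm).
#' @param physics a [proton_physics()] object.
#' @return a [pbs_plan()] with attribute `diagnostics` (achieved distal
#'   90% depth, plateau flatness, layer table).
#' @export
optimize_sobp <- function(target_range_mm = 250, modulation_mm = 100,
                          prescription_gy = 2, beamline = beamline_config(),
                          field_mm = c(100, 100), layer_spacing_mm = 3,
                          spot_spacing_frac = 0.85, plateau_trim = 5,
                          physics = default_physics()) {
  stopifnot(modulation_mm <= target_range_mm, modulation_mm >= 0)
  rs <- beamline$range_shifter_wet
  build <- function(r_deep) {
    # layers span from the calibrated deepest range down to the proximal
    # edge of the modulation, which stays anchored to the requested range
    r_prox <- target_range_mm - modulation_mm
    n_layers <- if (modulation_mm == 0) 1 else
      max(2, floor((r_deep - r_prox) / layer_spacing_mm) + 1)
    ranges <- seq(r_deep, by = -layer_spacing_mm, length.out = n_layers)
    energies <- unique(vapply(ranges, function(r)
      snap_energy(beamline, proton_energy_from_range(r + rs, physics)), 0))
    energies
  }
  axis_dose_matrix <- function(energies, z) {
    # central-axis dose per unit layer weight (lateral lattice folded in)
    A <- matrix(0, length(z), length(energies))
    lattices <- vector("list", length(energies))
    for (li in seq_along(energies)) {
      E <- energies[li]
      sig0 <- spot_sigma_air(beamline, E)
      lat <- layer_lattice(c(-field_mm[1] / 2, field_mm[1] / 2),
                           c(-field_mm[2] / 2, field_mm[2] / 2), sig0,
                           spot_spacing_frac)
      wx <- lateral_weights_1d(lat$x, sig0, -field_mm[1] / 2, field_mm[1] / 2)
      wy <- lateral_weights_1d(lat$y, sig0, -field_mm[2] / 2, field_mm[2] / 2)
      curve <- bragg_idd(E, beamline = beamline, physics = physics)
      sigz <- fe_sigma_profile(E, wed = z, rsp = 1, x0_mm = physics$x0_water_mm,
                               rs_wet = rs, sigma0 = sig0, physics = physics)
      iddz <- idd_value(curve, rs + z)
      gx <- rowSums(exp(-outer(rep(0, length(z)), lat$x, "-")^2 /
                          (2 * sigz^2)) * rep(wx, each = length(z)))
      gy <- rowSums(exp(-outer(rep(0, length(z)), lat$y, "-")^2 /
                          (2 * sigz^2)) * rep(wy, each = length(z)))
      A[, li] <- iddz * gx * gy / (2 * pi * sigz^2)
      lattices[[li]] <- list(x = lat$x, y = lat$y, wx = wx, wy = wy)
    }
    list(A = A, lattices = lattices)
  }

  z <- seq(1, target_range_mm + 30, by = 1)
  r_deep <- target_range_mm
  energies <- build(r_deep)
  for (iter in 1:3) {
    ad <- axis_dose_matrix(energies, z)
    plateau <- z >= (target_range_mm - modulation_mm + plateau_trim) &
      z <= (target_range_mm - plateau_trim)
    # the fit extends closer to the distal end so the deepest layer's weight
    # is pinned by the plateau objective rather than left free
    fitreg <- z >= (target_range_mm - modulation_mm + plateau_trim) &
      z <= (r_deep - 2)
    if (length(energies) == 1) {
      w <- prescription_gy / max(ad$A[, 1])
      profile <- ad$A[, 1] * w
      w <- matrix(w)
      flat <- NA_real_
    } else {
      fit <- pracma::lsqnonneg(ad$A[fitreg, , drop = FALSE], rep(1, sum(fitreg)))
      w <- fit$x
      if (all(w == 0)) stop("SOBP optimization failed: all layer weights zero")
      profile <- as.numeric(ad$A %*% w)
      s <- prescription_gy / mean(profile[plateau])
      w <- w * s
      profile <- profile * s
      flat <- max(abs(profile[plateau] - prescription_gy)) / prescription_gy
    }
    # distal 90% point, searched on the distal half so rippled stacks with a
    # towering proximal layer cannot hijack the crossing
    dsel <- z >= target_range_mm - modulation_mm / 2
    d90 <- distal_falloff_depth(z[dsel], profile[dsel],
                                0.9 * max(1e-12, mean(profile[plateau])) /
                                  max(profile[dsel]))
    if (length(energies) == 1 || is.na(d90))
      d90 <- distal_falloff_depth(z[dsel], profile[dsel], 0.9)
    if (is.na(d90)) stop("SOBP optimization failed: no distal falloff found")
    err <- target_range_mm - d90
    err <- max(-2 * layer_spacing_mm, min(2 * layer_spacing_mm, err))
    if (abs(err) < 0.25 || iter == 3) break
    r_deep <- r_deep + err
    energies <- build(r_deep)
  }

  keep <- which(w > 1e-9 * max(w))
  layers <- lapply(keep, function(li) {
    lat <- ad$lattices[[li]]
    sp <- expand.grid(x = lat$x, y = lat$y)
    sp$weight <- as.numeric(outer(lat$wx, lat$wy)) * w[li]
    sp <- sp[sp$weight > 1e-9 * max(sp$weight), ]
    list(energy = energies[li], spots = sp)
  })
  plan <- pbs_plan(list(list(direction = c(0, 0, 1), beamline = beamline,
                             layers = layers)),
                   label = sprintf("sobp_R%.0f_M%.0f", target_range_mm, modulation_mm))
  attr(plan, "diagnostics") <- list(
    distal90_mm = d90, flatness = flat, n_layers = length(energies),
    energies = energies, layer_weights = as.numeric(w),
    axis_profile = data.frame(z = z, dose = profile))
  plan
}

#' Create a uniform-dose plan for a box target
#'
#' Mirrors the planning workflow used for heterogeneous phantoms: the
#' heterogeneity volumes are (optionally) overridden to water, a spot
#' lattice and energy-layer stack covering the target are constructed, and
#' layer weights are optimized with the APB model for a uniform target
#' dose; removing the override afterwards yields the deliberately
#' nonuniform delivered distribution.
#'
#' @param phantom a [voxel_phantom()].
#' @param target_box list with `x`, `y`, `z` two-vectors (mm, phantom
#'   coordinates).
#' @param beamline a [beamline_config()].
#' @param prescription_gy target dose (Gy).
#' @param override_to_water override the phantom's heterogeneity mask to
#'   water during optimization (default TRUE).
#' @param layer_spacing_mm spacing of layer ranges (mm WET).
#' @param spot_spacing_frac lattice spacing as a fraction of sigma.
#' @param margin_sigma lateral lattice margin in units of sigma.
#' @param uniform_tol warn if the optimized (override) target dose spread
#'   exceeds this fraction (default 0.03).
#' @param label plan label.
#' @param physics a [proton_physics()] object.
#' @return a [pbs_plan()] with attribute `diagnostics` (target dose spread
#'   under the optimization phantom, layer table).
#' @export
create_uniform_plan <- function(phantom, target_box, beamline,
                                prescription_gy = 2, override_to_water = TRUE,
                                layer_spacing_mm = 2.5, spot_spacing_frac = 0.85,
                                margin_sigma = 1.2, uniform_tol = 0.03,
                                label = "uniform", physics = default_physics()) {
  ax <- phantom_axes(phantom)
  for (a in 1:3) {
    lim <- range(ax[[a]])
    bx <- target_box[[c("x", "y", "z")[a]]]
    if (bx[1] < lim[1] - phantom$spacing[a] || bx[2] > lim[2] + phantom$spacing[a])
      stop("target box extends outside the phantom")
  }
  ph_opt <- if (override_to_water) override_heterogeneity(phantom) else phantom
  rs <- beamline$range_shifter_wet

  # WET span of the target over its lateral footprint
  xs <- seq(target_box$x[1], target_box$x[2], length.out = 5)
  ys <- seq(target_box$y[1], target_box$y[2], length.out = 5)
  wed_lo <- wed_hi <- NULL
  for (x in xs) for (y in ys) {
    w2 <- wed_column(ph_opt, x, y, target_box$z)
    wed_lo <- c(wed_lo, w2[1]); wed_hi <- c(wed_hi, w2[2])
  }
  r_min <- min(wed_lo) - 1
  r_max <- max(wed_hi) + 1
  ranges <- rev(seq(r_max, r_min, by = -layer_spacing_mm))
  energies <- unique(vapply(ranges + rs,
                            function(r) snap_energy(beamline,
                                                    proton_energy_from_range(r, physics)), 0))

  # per-layer lattice with edge-enhanced lateral weights
  layers <- lapply(energies, function(E) {
    sig0 <- spot_sigma_air(beamline, E)
    lat <- layer_lattice(target_box$x, target_box$y, sig0, spot_spacing_frac,
                         margin_sigma)
    wx <- lateral_weights_1d(lat$x, sig0, target_box$x[1], target_box$x[2])
    wy <- lateral_weights_1d(lat$y, sig0, target_box$y[1], target_box$y[2])
    sp <- expand.grid(x = lat$x, y = lat$y)
    sp$weight <- as.numeric(outer(wx, wy))
    sp <- sp[sp$weight > 1e-6, ]
    list(energy = E, spots = sp)
  })

  # layer weights: NNLS against uniform dose at target sample points
  tp <- expand.grid(x = seq(target_box$x[1], target_box$x[2], length.out = 5),
                    y = seq(target_box$y[1], target_box$y[2], length.out = 5),
                    z = seq(target_box$z[1] + 1, target_box$z[2] - 1,
                            length.out = max(4, ceiling(diff(target_box$z) / 3))))
  cols <- unique(tp[c("x", "y")])
  wed_pts <- numeric(nrow(tp))
  for (ci in seq_len(nrow(cols))) {
    sel <- tp$x == cols$x[ci] & tp$y == cols$y[ci]
    wed_pts[sel] <- wed_column(ph_opt, cols$x[ci], cols$y[ci], tp$z[sel])
  }
  A <- matrix(0, nrow(tp), length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    sig0 <- spot_sigma_air(beamline, l$energy)
    curve <- bragg_idd(l$energy, beamline = beamline, physics = physics)
    zq <- seq(0, max(target_box$z) + 5, by = 2)
    wed_axis <- wed_column(ph_opt, mean(target_box$x), mean(target_box$y), zq)
    sigq <- fe_sigma_profile(l$energy, z = zq, wed = wed_axis, rsp = 1,
                             x0_mm = physics$x0_water_mm, rs_wet = rs,
                             sigma0 = sig0, physics = physics)
    sig_pt <- approx(zq, sigq, xout = tp$z, rule = 2)$y
    iddp <- idd_value(curve, rs + wed_pts)
    d2 <- outer(tp$x, l$spots$x, "-")^2 + outer(tp$y, l$spots$y, "-")^2
    g <- exp(-d2 / (2 * sig_pt^2)) %*% l$spots$weight
    A[, li] <- iddp * as.numeric(g) / (2 * pi * sig_pt^2)
  }
  fit <- pracma::lsqnonneg(A, rep(1, nrow(tp)))
  wl <- fit$x
  if (all(wl == 0)) stop("uniform-plan optimization failed: zero weights")
  dose <- as.numeric(A %*% wl)
  s <- prescription_gy / mean(dose)
  wl <- wl * s
  dose <- dose * s
  spread <- (max(dose) - min(dose)) / prescription_gy
  if (override_to_water && spread > 2 * uniform_tol)
    warning(sprintf("optimized target dose spread %.1f%% exceeds tolerance", 100 * spread))

  keep <- which(wl > 1e-9 * max(wl))
  layers <- lapply(keep, function(li) {
    l <- layers[[li]]
    l$spots$weight <- l$spots$weight * wl[li]
    l
  })
  plan <- pbs_plan(list(list(direction = c(0, 0, 1), beamline = beamline,
                             layers = layers)), label = label)
  attr(plan, "diagnostics") <- list(
    target_dose_spread = spread, max_dev = max(abs(dose - prescription_gy)) / prescription_gy,
    energies = energies[keep], layer_weights = wl[keep], n_target_points = nrow(tp))
  plan
}

#' Remove random spots or layers from a plan
#'
#' Creates a degraded copy (the original is untouched) by removing
#' `ceiling(fraction * N)` spots, or energy layers, uniformly at random
#' under the given seed. Used to build deliberately nonuniform,
#' high-gradient test plans from uniform ones.
#'
#' @param plan a [pbs_plan()].
#' @param mode `"spots"` or `"layers"`.
#' @param fraction fraction to remove, in `[0, 1)`.
#' @param seed RNG seed (isolated from the caller's RNG state).
#' @return a [pbs_plan()].
#' @export
degrade_plan <- function(plan, mode = c("spots", "layers"), fraction, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(plan)
  out <- plan
  for (bi in seq_along(plan$beams)) {
    b <- plan$beams[[bi]]
    if (mode == "layers") {
      nl <- length(b$layers)
      nrm <- ceiling(fraction * nl)
      if (nrm >= nl) stop("removal would empty the plan")
      drop <- with_seed(seed + bi, sample(nl, nrm))
      out$beams[[bi]]$layers <- b$layers[-drop]
    } else {
      ns <- vapply(b$layers, function(l) nrow(l$spots), 0L)
      tot <- sum(ns)
      nrm <- ceiling(fraction * tot)
      if (nrm >= tot) stop("removal would empty the plan")
      drop <- with_seed(seed + bi, sample(tot, nrm))
      off <- cumsum(c(0, ns))
      keep_layers <- list()
      for (li in seq_along(b$layers)) {
        ids <- (off[li] + 1):(off[li] + ns[li])
        keep <- !(ids %in% drop)
        if (any(keep)) {
          l <- b$layers[[li]]
          l$spots <- l$spots[keep, , drop = FALSE]
          keep_layers[[length(keep_layers) + 1]] <- l
        }
      }
      out$beams[[bi]]$layers <- keep_layers
    }
  }
  out$label <- sprintf("%s_deg_%s%.0f", plan$label, substr(mode, 1, 1),
                       100 * fraction)
  out
}

#' Write / read a plan as JSON
#'
#' Round-trip-stable plan schema: beams with direction and beamline
#' parameters, layers with energy and spot (x, y, weight) triples.
#'
#' @param plan a [pbs_plan()].
#' @param path file path.
#' @return [read_plan()] returns a [pbs_plan()].
#' @export
write_plan <- function(plan, path) {
  ser <- list(label = plan$label, beams = lapply(plan$beams, function(b)
    list(direction = b$direction, beamline = unclass(b$beamline),
         layers = lapply(b$layers, function(l)
           list(energy = l$energy, x = l$spots$x, y = l$spots$y,
                weight = l$spots$weight)))))
  writeLines(jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  beams <- lapply(j$beams, function(b) {
    args <- b$beamline[names(b$beamline) %in% names(formals(beamline_config))]
    if (!is.null(args$sigma_air_params))
      args$sigma_air_params <- stats::setNames(unlist(args$sigma_air_params),
                                               c("a", "b", "eref"))
    bl <- do.call(beamline_config, args)
    layers <- lapply(b$layers, function(l)
      list(energy = l$energy,
           spots = data.frame(x = unlist(l$x), y = unlist(l$y),
                              weight = unlist(l$weight))))
    list(direction = unlist(b$direction), beamline = bl, layers = layers)
  })
  pbs_plan(beams, label = j$label)
}
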