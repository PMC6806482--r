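#' Gamma analysis criterion
#'
#' Global gamma: the dose-difference tolerance and inclusion threshold are
#' percentages of a single normalization level, the maximum of the
#' computed (evaluation) dose.
#'
#' @param dose_percent dose-difference criterion (% of normalization).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param threshold_percent reference points below this % of normalization
#'   are excluded (5 is customary for 2D, 10 for 3D analyses).
#' @param search_factor search radius in units of `dta_mm` (default 3).
#' @param sub_step_frac evaluation sub-sampling step as a fraction of
#'   `dta_mm` (default 0.1).
#' @return object of class `gamma_criterion`.
#' @export
gamma_criterion <- function(dose_percent, dta_mm, threshold_percent = 5,
                            search_factor = 3, sub_step_frac = 0.1) {
  stopifnot(dose_percent > 0, dta_mm > 0,
            threshold_percent >= 0, threshold_percent < 100)
  structure(list(dose_percent = dose_percent, dta_mm = dta_mm,
                 threshold_percent = threshold_percent,
                 search_factor = search_factor,
                 sub_step_frac = sub_step_frac),
            class = "gamma_criterion")
}

#' @export
print.gamma_criterion <- function(x, ...) {
  cat(sprintf("gamma criterion: %g%%/%g mm, threshold %g%%\n",
              x$dose_percent, x$dta_mm, x$threshold_percent))
  invisible(x)
}

format_criterion <- function(cr) sprintf("%g%%/%gmm", cr$dose_percent, cr$dta_mm)

gamma_result <- function(gamma, criterion, roles, n_excluded = 0) {
  g <- gamma[!is.na(gamma)]
  if (length(g) == 0) stop("empty analysis: no reference points above threshold")
  structure(list(pass_rate = 100 * mean(g <= 1), mean_gamma = mean(g),
                 n_included = length(g), n_excluded = n_excluded,
                 criterion = criterion, roles = roles),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %s: pass rate %.1f%% (n = %d), mean gamma %.3f\n",
              format_criterion(x$criterion), x$pass_rate, x$n_included,
              x$mean_gamma))
  invisible(x)
}

#' Extract a 2D dose plane from a cube
#'
#' Linear interpolation in depth between the two neighboring z slices,
#' then bilinear resampling onto the requested lattice.
#'
#' @param cube a [dose_cube()].
#' @param depth_z absolute z of the plane in cube coordinates (mm).
#' @param x,y lattice coordinates (mm).
#' @return matrix of dose values (`length(x)` by `length(y)`).
#' @export
extract_plane <- function(cube, depth_z, x, y) {
  ax <- cube_axes(cube)
  zc <- ax[[3]]
  if (depth_z < zc[1] - cube$spacing[3] / 2 || depth_z > zc[length(zc)] + cube$spacing[3] / 2)
    stop(sprintf("depth %.2f mm outside cube z extent [%.2f, %.2f]",
                 depth_z, zc[1], zc[length(zc)]))
  k <- findInterval(depth_z, zc)
  if (k < 1) { k <- 1; w <- 0 }
  else if (k >= length(zc)) { k <- length(zc) - 1; w <- 1 }
  else w <- (depth_z - zc[k]) / (zc[k + 1] - zc[k])
  sl <- cube$dose[, , k] * (1 - w) + cube$dose[, , k + 1] * w
  bilinear_resample(sl, ax[[1]], ax[[2]], x, y)
}

#' 2D global gamma analysis
#'
#' The measured plane is the reference ("measured doses as reference, the
#' computed doses as comparison"); the computed plane is the evaluation
#' whose maximum defines the global normalization. A measured plane on the
#' detector pitch is first linearly interpolated to a 2-mm grid. For every
#' reference point above the threshold, the gamma index is minimized over
#' evaluation positions within `search_factor * dta` of the point,
#' sub-sampled at `sub_step_frac * dta` by bilinear interpolation.
#'
#' @param reference a `measured_plane`, or a list with `values`, `x`, `y`.
#' @param evaluation a list with `values`, `x`, `y` (computed plane on a
#'   regular grid), e.g. from [extract_plane()].
#' @param criterion a [gamma_criterion()].
#' @param interp_spacing grid to which a detector-pitch reference is
#'   interpolated (mm).
#' @return a `gamma_result`; attribute `gamma_map` carries the per-point
#'   gamma values (NA below threshold) on the reference grid.
#' @export
gamma_2d <- function(reference, evaluation, criterion = gamma_criterion(3, 3),
                     interp_spacing = 2) {
  if (inherits(reference, "measured_plane") && reference$pitch > interp_spacing)
    reference <- interp_plane_to_grid(reference, interp_spacing)
  ev <- evaluation$values
  norm <- max(ev)
  if (!is.finite(norm) || norm <= 0) stop("evaluation dose has no positive maximum")
  tol <- criterion$dose_percent / 100 * norm
  thr <- criterion$threshold_percent / 100 * norm
  rx <- reference$x; ry <- reference$y
  rv <- reference$values
  pts <- which(rv >= thr, arr.ind = TRUE)
  if (nrow(pts) == 0) stop("empty analysis: no reference points above threshold")
  coords <- cbind(rx[pts[, 1]], ry[pts[, 2]])
  g <- gamma2d_min_cpp(rv[pts], coords, ev, evaluation$x[1], evaluation$y[1],
                       evaluation$x[2] - evaluation$x[1],
                       evaluation$y[2] - evaluation$y[1], tol,
                       criterion$dta_mm,
                       criterion$search_factor * criterion$dta_mm,
                       criterion$sub_step_frac * criterion$dta_mm)
  res <- gamma_result(g, criterion,
                      roles = c(reference = "measured", evaluation = "computed"))
  gm <- matrix(NA_real_, nrow(rv), ncol(rv))
  gm[pts] <- g
  attr(res, "gamma_map") <- list(values = gm, x = rx, y = ry)
  res
}

#' 3D global gamma analysis with sparse reference points
#'
#' The sparsely measured points are the reference and the computed cube is
#' the evaluation (the converse of the 2D analysis roles); normalization is
#' the cube maximum and the customary threshold is 10%. The gamma search
#' explores the full 3D neighborhood, including the depth direction.
#'
#' @param ref_points data frame with `x`, `y`, `z` (mm, cube coordinates)
#'   and `dose` (Gy), e.g. a measured plane's lattice at its plane z.
#' @param cube evaluation [dose_cube()].
#' @param criterion a [gamma_criterion()] (threshold customarily 10).
#' @return a `gamma_result` (excluded out-of-cube points are counted).
#' @export
gamma_3d <- function(ref_points, cube,
                     criterion = gamma_criterion(3, 3, threshold_percent = 10)) {
  norm <- max(cube$dose)
  if (norm <= 0) stop("evaluation cube has no positive dose")
  tol <- criterion$dose_percent / 100 * norm
  thr <- criterion$threshold_percent / 100 * norm
  ax <- cube_axes(cube)
  margin <- criterion$search_factor * criterion$dta_mm
  inside <- ref_points$x >= min(ax[[1]]) & ref_points$x <= max(ax[[1]]) &
    ref_points$y >= min(ax[[2]]) & ref_points$y <= max(ax[[2]]) &
    ref_points$z >= min(ax[[3]]) - margin & ref_points$z <= max(ax[[3]]) + margin
  n_excl <- sum(!inside)
  if (n_excl > 0)
    warning(sprintf("%d reference point(s) outside the cube excluded", n_excl))
  rp <- ref_points[inside & ref_points$dose >= thr, , drop = FALSE]
  if (nrow(rp) == 0) stop("empty analysis: no reference points above threshold")
  g <- gamma3d_min_cpp(rp$dose, as.matrix(rp[c("x", "y", "z")]),
                       as.numeric(cube$dose), as.integer(cube$dims),
                       cube$spacing, cube$origin, tol, criterion$dta_mm,
                       criterion$search_factor * criterion$dta_mm,
                       criterion$sub_step_frac * criterion$dta_mm)
  gamma_result(g, criterion,
               roles = c(reference = "measured points", evaluation = "computed cube"),
               n_excluded = n_excl)
}

#' Depth-of-best-agreement search
#'
#' Scans extraction depths around the expected depth `d_e` of the
#' measurement plane in the dose cube, running the 2D gamma analysis at
#' each, and returns the depth of best agreement `d_gamma`: maximal pass
#' rate, ties broken by minimal mean gamma, then by proximity to `d_e`.
#'
#' @param measured a `measured_plane`.
#' @param cube computed [dose_cube()].
#' @param criterion a [gamma_criterion()] for the scan.
#' @param d_e expected depth of the plane below the cube's upstream face
#'   (mm); default derived from the measured plane's `z_plane`.
#' @param window search half-width (mm), default 5.
#' @param step search step (mm), default 0.1.
#' @param interp_spacing comparison grid spacing (mm).
#' @param pass_tol,gamma_tol tie tolerances: depths whose pass rate is
#'   within `pass_tol` percentage points of the best, and whose mean gamma
#'   is within `gamma_tol` of the best among those, are treated as
#'   statistically tied and resolved by proximity to `d_e` (flat dose
#'   regions would otherwise be decided by measurement noise).
#' @return object of class `depth_search_result`: `d_m`, `d_e`, `d_gamma`,
#'   `delta` (= d_e - d_gamma) and the per-depth trace.
#' @export
depth_search <- function(measured, cube, criterion = gamma_criterion(3, 3),
                         d_e = NULL, window = 5, step = 0.1,
                         interp_spacing = 2, pass_tol = 1, gamma_tol = 0.02) {
  zf <- cube_z_front(cube)
  if (is.null(d_e)) {
    if (is.na(measured$z_plane)) stop("d_e not derivable: measured plane has no z_plane")
    d_e <- measured$z_plane - zf
  }
  ref <- interp_plane_to_grid(measured, interp_spacing)
  margin <- criterion$search_factor * criterion$dta_mm
  ex <- seq(min(ref$x) - margin, max(ref$x) + margin, by = interp_spacing)
  ey <- seq(min(ref$y) - margin, max(ref$y) + margin, by = interp_spacing)
  ax <- cube_axes(cube)
  offs <- seq(-window, window, by = step)
  zs <- zf + d_e + offs
  ok <- zs >= min(ax[[3]]) & zs <= max(ax[[3]])
  if (!all(ok)) {
    warning("search window truncated to the cube z extent")
    offs <- offs[ok]; zs <- zs[ok]
  }
  if (length(zs) == 0) stop("search window lies outside the cube")
  pass <- meang <- numeric(length(zs))
  for (i in seq_along(zs)) {
    ev <- list(values = extract_plane(cube, zs[i], ex, ey), x = ex, y = ey)
    r <- gamma_2d(ref, ev, criterion, interp_spacing)
    pass[i] <- r$pass_rate
    meang[i] <- r$mean_gamma
  }
  cand <- which(pass >= max(pass) - pass_tol)
  cand <- cand[meang[cand] <= min(meang[cand]) + gamma_tol]
  best <- cand[which.min(abs(offs[cand]))]
  d_gamma <- d_e + offs[best]
  structure(list(d_m = measured$d_m, d_e = d_e, d_gamma = d_gamma,
                 delta = d_e - d_gamma, criterion = criterion,
                 trace = data.frame(depth = d_e + offs, pass_rate = pass,
                                    mean_gamma = meang)),
            class = "depth_search_result")
}

#' @export
print.depth_search_result <- function(x, ...) {
  cat(sprintf("depth search: d_m %.2f, d_e %.2f, d_gamma %.2f, d_e - d_gamma %+.2f mm (%s)\n",
              x$d_m, x$d_e, x$d_gamma, x$delta, format_criterion(x$criterion)))
  invisible(x)
}
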