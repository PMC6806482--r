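# Gamma analysis: oracle equivalence, invariances and the depth search

# independent brute-force gamma: plain nested search over the same candidate
# lattice definition (search radius, sub-step, bilinear interpolation)
brute_gamma_2d <- function(ref_vals, ref_x, ref_y, ev, ex, ey, crit) {
  norm <- max(ev)
  tol <- crit$dose_percent / 100 * norm
  thr <- crit$threshold_percent / 100 * norm
  rad <- crit$search_factor * crit$dta_mm
  sub <- crit$sub_step_frac * crit$dta_mm
  offs <- expand.grid(ox = seq(-rad, rad, by = sub), oy = seq(-rad, rad, by = sub))
  offs <- offs[offs$ox^2 + offs$oy^2 <= rad^2, ]
  interp <- function(px, py) {
    fx <- (px - ex[1]) / (ex[2] - ex[1]); fy <- (py - ey[1]) / (ey[2] - ey[1])
    i <- floor(fx); j <- floor(fy)
    if (i + 1 == length(ex) && fx <= length(ex) - 1 + 1e-9) i <- i - 1
    if (j + 1 == length(ey) && fy <= length(ey) - 1 + 1e-9) j <- j - 1
    if (i < 0 || j < 0 || i + 1 >= length(ex) || j + 1 >= length(ey)) return(NA)
    wx <- fx - i; wy <- fy - j
    ev[i + 1, j + 1] * (1 - wx) * (1 - wy) + ev[i + 2, j + 1] * wx * (1 - wy) +
      ev[i + 1, j + 2] * (1 - wx) * wy + ev[i + 2, j + 2] * wx * wy
  }
  out <- matrix(NA_real_, length(ref_x), length(ref_y))
  for (a in seq_along(ref_x)) for (b in seq_along(ref_y)) {
    if (ref_vals[a, b] < thr) next
    best <- Inf
    for (o in seq_len(nrow(offs))) {
      dv <- interp(ref_x[a] + offs$ox[o], ref_y[b] + offs$oy[o])
      if (is.na(dv)) next
      g2 <- (dv - ref_vals[a, b])^2 / tol^2 +
        (offs$ox[o]^2 + offs$oy[o]^2) / crit$dta_mm^2
      if (g2 < best) best <- g2
    }
    out[a, b] <- sqrt(best)
  }
  out
}

smooth_plane <- function(nx, ny, seed, amp = 1) {
  set.seed(seed)
  x <- seq_len(nx); y <- seq_len(ny)
  f <- outer(x, y, function(i, j)
    amp * (1 + 0.5 * sin(i / 3 + runif(1)) * cos(j / 4 + runif(1)) +
             0.2 * sin(i * j / 40)))
  pmax(f, 0)
}

test_that("gamma of a distribution against itself is identically zero", {
  v <- smooth_plane(15, 15, 1)
  pl <- list(values = v, x = seq(0, 28, by = 2), y = seq(0, 28, by = 2))
  r <- gamma_2d(pl, pl, gamma_criterion(3, 3))
  expect_equal(r$pass_rate, 100)
  expect_equal(r$mean_gamma, 0, tolerance = 1e-12)
})

test_that("a 2% global rescale passes 2%/2 mm everywhere", {
  v <- smooth_plane(20, 18, 2)
  xs <- seq(0, 38, by = 2); ys <- seq(0, 34, by = 2)
  ref <- list(values = v, x = xs, y = ys)
  ev <- list(values = v * 1.02, x = xs, y = ys)
  r <- gamma_2d(ref, ev, gamma_criterion(2, 2, threshold_percent = 5))
  expect_equal(r$pass_rate, 100)
})

test_that("the fast 2D search equals the brute-force oracle", {
  crit <- gamma_criterion(3, 2, threshold_percent = 10, sub_step_frac = 0.25)
  for (seed in 1:3) {
    xs <- seq(0, 38, by = 2); ys <- seq(0, 38, by = 2)
    ref <- list(values = smooth_plane(20, 20, seed), x = xs, y = ys)
    ev <- list(values = smooth_plane(20, 20, seed + 50), x = xs, y = ys)
    r <- gamma_2d(ref, ev, crit)
    gm <- attr(r, "gamma_map")$values
    oracle <- brute_gamma_2d(ref$values, xs, ys, ev$values, xs, ys, crit)
    expect_equal(gm, oracle, tolerance = 1e-9)
  }
})

test_that("3D gamma matches a brute-force all-candidate search", {
  set.seed(11)
  dims <- c(10, 10, 10)
  cube <- dose_cube(array(runif(1000, 0.2, 1), dims), c(2, 2, 2), c(0, 0, 0),
                    engine = "apb")
  pts <- expand.grid(x = c(4, 8, 12), y = c(4, 10), z = c(6, 12))
  pts$dose <- runif(nrow(pts), 0.3, 1)
  crit <- gamma_criterion(3, 3, threshold_percent = 10, sub_step_frac = 0.5)
  r <- gamma_3d(pts, cube, crit)
  # oracle: direct minimization over the same 3D candidate lattice
  rad <- crit$search_factor * crit$dta_mm
  sub <- crit$sub_step_frac * crit$dta_mm
  offs <- expand.grid(ox = seq(-rad, rad, by = sub),
                      oy = seq(-rad, rad, by = sub),
                      oz = seq(-rad, rad, by = sub))
  offs <- offs[offs$ox^2 + offs$oy^2 + offs$oz^2 <= rad^2, ]
  tol <- crit$dose_percent / 100 * max(cube$dose)
  tri <- function(p) {
    f <- (p - cube$origin) / cube$spacing
    i <- floor(f)
    i <- ifelse(i + 1 == dims & f <= dims - 1 + 1e-9, i - 1, i)
    if (any(i < 0) || any(i + 1 >= dims)) return(NA)
    w <- f - i
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
      acc <- acc + cube$dose[i[1] + dx + 1, i[2] + dy + 1, i[3] + dz + 1] *
        (if (dx) w[1] else 1 - w[1]) * (if (dy) w[2] else 1 - w[2]) *
        (if (dz) w[3] else 1 - w[3])
    acc
  }
  g_oracle <- vapply(seq_len(nrow(pts)), function(q) {
    best <- Inf
    for (o in seq_len(nrow(offs))) {
      dv <- tri(c(pts$x[q] + offs$ox[o], pts$y[q] + offs$oy[o],
                  pts$z[q] + offs$oz[o]))
      if (is.na(dv)) next
      g2 <- (dv - pts$dose[q])^2 / tol^2 +
        (offs$ox[o]^2 + offs$oy[o]^2 + offs$oz[o]^2) / crit$dta_mm^2
      best <- min(best, g2)
    }
    sqrt(best)
  }, 0)
  pass_oracle <- 100 * mean(g_oracle <= 1)
  expect_equal(r$pass_rate, pass_oracle, tolerance = 1e-9)

  # identity: points lifted from the cube itself
  ax <- protonqa:::cube_axes(cube)
  pts2 <- expand.grid(x = ax[[1]][3:5], y = ax[[2]][4], z = ax[[3]][5])
  pts2$dose <- cube$dose[cbind(3:5, 4, 5)]
  expect_equal(gamma_3d(pts2, cube, crit)$pass_rate, 100)
})

test_that("a z-shift within DTA passes 3%/3 mm but not 2%/2 mm", {
  # steep depth gradient cube: dose falls linearly along z
  nz <- 40
  dose <- aperm(array(rep(seq(1, 0.2, length.out = nz), each = 225),
                      c(15, 15, nz)), c(1, 2, 3))
  cube <- dose_cube(dose, c(2, 2, 1), c(0, 0, 0), engine = "apb")
  ax <- protonqa:::cube_axes(cube)
  pts <- expand.grid(x = ax[[1]][4:12], y = ax[[2]][4:12], z = 15)
  shifted <- dose_cube(dose, c(2, 2, 1), c(0, 0, 2.5), engine = "apb")
  pts$dose <- cube$dose[cbind(match(pts$x, ax[[1]]), match(pts$y, ax[[2]]),
                              match(pts$z, ax[[3]]))]
  r33 <- gamma_3d(pts, shifted, gamma_criterion(3, 3, threshold_percent = 10))
  r22 <- gamma_3d(pts, shifted, gamma_criterion(2, 2, threshold_percent = 10))
  expect_equal(r33$pass_rate, 100)
  expect_lt(r22$pass_rate, 100)
})

test_that("gamma is anti-monotone across loosening criteria", {
  for (seed in 1:4) {
    xs <- seq(0, 30, by = 2)
    ref <- list(values = smooth_plane(16, 16, seed), x = xs, y = xs)
    ev <- list(values = smooth_plane(16, 16, seed + 9), x = xs, y = xs)
    p <- vapply(list(c(2, 2), c(3, 3), c(5, 3)), function(cd)
      gamma_2d(ref, ev, gamma_criterion(cd[1], cd[2], 5))$pass_rate, 0)
    expect_true(all(diff(p) >= 0))
  }
})

test_that("the gamma map is invariant under joint rescaling", {
  xs <- seq(0, 30, by = 2)
  ref <- list(values = smooth_plane(16, 16, 3), x = xs, y = xs)
  ev <- list(values = smooth_plane(16, 16, 12), x = xs, y = xs)
  crit <- gamma_criterion(3, 3)
  g1 <- attr(gamma_2d(ref, ev, crit), "gamma_map")$values
  ref2 <- ref; ev2 <- ev
  ref2$values <- ref$values * 3.7; ev2$values <- ev$values * 3.7
  g2 <- attr(gamma_2d(ref2, ev2, crit), "gamma_map")$values
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("gamma errors on an empty analysis", {
  xs <- seq(0, 10, by = 2)
  ref <- list(values = matrix(0.001, 6, 6), x = xs, y = xs)
  ev <- list(values = matrix(1, 6, 6), x = xs, y = xs)
  expect_error(gamma_2d(ref, ev, gamma_criterion(3, 3, 10)), "empty analysis")
})

# synthetic SOBP-edge cube for depth-search tests: lateral Gaussian, distal
# sigmoid falloff crossing the plane depths
search_cube <- function(z_edge = 30) {
  ax <- seq(-42, 42, by = 2)
  zs <- seq(0.5, 59.5, by = 1)
  dose <- array(0, c(length(ax), length(ax), length(zs)))
  for (k in seq_along(zs))
    dose[, , k] <- outer(ax, ax, function(x, y)
      2 * plogis((z_edge - zs[k]) / 3) * exp(-(x^2 + y^2) / 1800))
  dose_cube(dose, c(2, 2, 1), c(-42, -42, 0.5), engine = "apb",
            meta = list(surface_z = 0))
}

test_that("depth search recovers its own plane and injected shifts", {
  cube <- search_cube()
  meas <- simulate_measurement(cube, stack_mm = 20, surface_z = 0, n_det = 7,
                               noise_sigma = 0)
  ds <- depth_search(meas, cube, gamma_criterion(3, 3, 5), window = 5, step = 0.1)
  # detector-pitch resampling biases the optimum by a fraction of a mm
  expect_lte(abs(ds$delta), 0.5)
  expect_equal(ds$d_m, 20 * 1.03 + 6)

  # shifting the cube's content deeper (its front face, and hence the d_e
  # bookkeeping, staying where the measurement geometry put it) moves the
  # recovered delta by the injected amount
  shifted <- cube
  shifted$origin[3] <- cube$origin[3] + 1.0
  ds2 <- depth_search(meas, shifted, gamma_criterion(3, 3, 5),
                      window = 5, step = 0.1)
  expect_equal(ds2$delta - ds$delta, -1.0, tolerance = 0.15)
})

test_that("injected shifts are recovered within one step across noise seeds", {
  cube <- search_cube()
  shifts <- c(-2, -1, -0.5, 0.5, 1, 2)
  hits <- 0; total <- 0
  for (seed in 1:5) {
    meas <- simulate_measurement(cube, stack_mm = 20, surface_z = 0, n_det = 7,
                                 noise_sigma = 0.01, seed = 100 * seed)
    ds0 <- depth_search(meas, cube, gamma_criterion(3, 3, 5),
                        window = 4, step = 0.2)
    for (sh in shifts) {
      shifted <- cube
      shifted$origin[3] <- cube$origin[3] + sh
      ds <- depth_search(meas, shifted, gamma_criterion(3, 3, 5),
                         window = 4, step = 0.2)
      total <- total + 1
      if (abs((ds$delta - ds0$delta) + sh) <= 0.2 + 1e-9) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("extract_plane interpolates linearly in depth", {
  cube <- search_cube()
  ax <- protonqa:::cube_axes(cube)
  xs <- ax[[1]][10:20]
  p1 <- extract_plane(cube, 10.5, xs, xs)  # on a voxel-center slice
  expect_equal(p1, cube$dose[10:20, 10:20, 11], tolerance = 1e-12)
  pm <- extract_plane(cube, 11, xs, xs)
  expect_equal(pm, (cube$dose[10:20, 10:20, 11] + cube$dose[10:20, 10:20, 12]) / 2,
               tolerance = 1e-12)
  expect_error(extract_plane(cube, 500, xs, xs), "outside cube")
})
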