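# Analytical pencil-beam engine: factorization, Fermi-Eyges widths and the
# deliberate blindness to off-axis heterogeneity

test_that("a single spot factorizes into IDD times a normalized Gaussian", {
  ph <- build_slab_phantom(list(list("water", 160)), lateral_size = 81,
                           spacing = 1)
  bl <- beamline_config()
  ax <- protonqa:::phantom_axes(ph)
  x0 <- ax[[1]][41] # place the spot exactly on a voxel center
  plan <- pbs_plan(list(list(direction = c(0, 0, 1), beamline = bl,
                             layers = list(list(energy = 150,
                                                spots = data.frame(x = x0, y = x0,
                                                                   weight = 2))))), "p")
  cube <- compute_dose_apb(plan, ph)
  idd <- bragg_idd(150, beamline = bl)
  zc <- protonqa:::cube_axes(cube)[[3]]
  sig <- fe_sigma_profile(150, z = zc, wed = zc, sigma0 = spot_sigma_air(bl, 150))
  axis_dose <- cube$dose[41, 41, ]
  pred <- 2 * protonqa:::idd_value(idd, zc) / (2 * pi * sig^2)
  sel <- pred > 0.05 * max(pred)
  expect_equal(axis_dose[sel], pred[sel], tolerance = 0.01)
})

test_that("the lateral width follows an independent Fermi-Eyges integral", {
  fx <- list(E = 150, z0 = 100)
  ph <- build_slab_phantom(list(list("water", 160)), lateral_size = 101,
                           spacing = 1)
  bl <- beamline_config()
  ax <- protonqa:::phantom_axes(ph)
  x0 <- ax[[1]][51]
  plan <- pbs_plan(list(list(direction = c(0, 0, 1), beamline = bl,
                             layers = list(list(energy = fx$E,
                                                spots = data.frame(x = x0, y = x0,
                                                                   weight = 1))))), "p")
  cube <- compute_dose_apb(plan, ph)
  k <- which.min(abs(protonqa:::cube_axes(cube)[[3]] - fx$z0))
  prof <- cube$dose[, 51, k]
  xs <- ax[[1]] - x0
  # moment estimate of the Gaussian sigma
  sig_fit <- sqrt(sum(prof * xs^2) / sum(prof))
  # independent numeric Fermi-Eyges integral with the Highland scattering
  # power (fine Riemann sum, telescoped log factor)
  phys <- proton_physics()
  dz <- 0.05
  zq <- seq(dz / 2, fx$z0, by = dz)
  R0 <- proton_range(fx$E)
  Emid <- proton_energy_from_range(pmax(R0 - zq, 0.5))
  Gp <- (protonqa:::highland_G(zq + dz / 2) - protonqa:::highland_G(zq - dz / 2)) / dz
  Tq <- protonqa:::pv_factor2(Emid) * Gp / phys$x0_water_mm
  sig_fe <- sqrt(spot_sigma_air(bl, fx$E)^2 + sum(Tq * (fx$z0 - zq)^2 * dz))
  expect_equal(sig_fit, sig_fe, tolerance = 0.02)
})

test_that("the engine cannot see heterogeneity off the spot axis", {
  ph_w <- build_slab_phantom(list(list("water", 120)), lateral_size = 60,
                             spacing = 2)
  ph_het <- ph_w
  # bone block 15 mm off-axis, not intersecting the spot's central column
  ax <- protonqa:::phantom_axes(ph_het)
  ib <- which(ax[[1]] > 10 & ax[[1]] < 25)
  kb <- which(ax[[3]] > 30 & ax[[3]] < 50)
  ph_het$material_index[ib, , kb] <- protonqa:::material_row(ph_het$materials, "bone")
  plan <- pencil_plan(130)
  c_w <- compute_dose_apb(plan, ph_w)
  c_h <- compute_dose_apb(plan, ph_het)
  expect_identical(c_w$dose, c_h$dose)
})

test_that("dose is exactly linear in spot weight and mirror-symmetric", {
  ph <- build_slab_phantom(list(list("water", 120)), lateral_size = 60,
                           spacing = 2)
  bl <- beamline_config()
  mk <- function(w, xs) pbs_plan(list(list(
    direction = c(0, 0, 1), beamline = bl,
    layers = list(list(energy = 130,
                       spots = data.frame(x = xs, y = 0, weight = w))))), "p")
  c1 <- compute_dose_apb(mk(1, 0), ph)
  c2 <- compute_dose_apb(mk(2, 0), ph)
  expect_equal(c2$dose, 2 * c1$dose, tolerance = 1e-12)

  cs <- compute_dose_apb(mk(c(1, 1), c(-8, 8)), ph)
  flip <- cs$dose[rev(seq_len(cs$dims[1])), , ]
  expect_equal(cs$dose, flip, tolerance = 1e-9)
})

test_that("the lateral integral of a single-spot dose recovers the IDD", {
  ph <- build_slab_phantom(list(list("water", 160)), lateral_size = 120,
                           spacing = 2)
  plan <- pencil_plan(140)
  cube <- compute_dose_apb(plan, ph, trunc_nsigma = 6)
  idd <- bragg_idd(140, beamline = beamline_config())
  zc <- protonqa:::cube_axes(cube)[[3]]
  integ <- apply(cube$dose, 3, sum) * prod(cube$spacing[1:2])
  pred <- protonqa:::idd_value(idd, zc)
  sel <- pred > 0.02 * max(pred)
  expect_equal(integ[sel], pred[sel], tolerance = 0.005)
})

test_that("mini-beam splitting and the halo option behave consistently", {
  ph <- build_slab_phantom(list(list("water", 120)), lateral_size = 60,
                           spacing = 2)
  plan <- pencil_plan(130)
  base <- compute_dose_apb(plan, ph)
  # in homogeneous water a sub-pencil bundle reproduces the single pencil
  # (the finite Gaussian mixture is a few-percent approximation by design)
  split2 <- compute_dose_apb(plan, ph, subspots = 2)
  sel <- base$dose > 0.3 * max(base$dose)
  expect_lt(max(abs(split2$dose[sel] - base$dose[sel])) / max(base$dose), 0.05)
  # halo off is the default; halo on preserves the laterally integrated dose
  halo <- compute_dose_apb(plan, ph, halo_fraction = 0.1, trunc_nsigma = 6)
  i0 <- apply(base$dose, 3, sum)
  ih <- apply(halo$dose, 3, sum)
  keep <- i0 > 0.05 * max(i0)
  expect_equal(ih[keep], i0[keep], tolerance = 0.02)
  expect_true(max(halo$dose) < max(base$dose)) # fluence moved into the halo
})
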