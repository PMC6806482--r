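# IDD curves, SOBP optimization, uniform plans and plan degradation

test_that("the Bragg curve peaks where the range-energy power law says", {
  idd <- bragg_idd(150)
  # independent power-law oracle for the distal 80% depth
  r_oracle <- 10 * 0.0022 * 150^1.77
  d80 <- protonqa:::distal_falloff_depth(idd$depth, idd$dose_per_mu, 0.8)
  expect_lt(abs(d80 - r_oracle), 2)
  expect_true(all(idd$dose_per_mu >= 0))
  # unimodal to numerical tolerance: rises to the peak, falls after it
  d <- idd$dose_per_mu
  ipk <- which.max(d)
  tol <- 5e-3 * max(d)
  expect_true(all(diff(d[1:ipk]) >= -tol))
  expect_true(all(diff(d[ipk:length(d)]) <= tol))
})

test_that("a 75-mm range shifter pulls the distal falloff 75 mm shallower", {
  bl0 <- beamline_config(range_shifter_wet = 0)
  bl75 <- beamline_config(range_shifter_wet = 75)
  mk <- function(bl) pbs_plan(list(list(
    direction = c(0, 0, 1), beamline = bl,
    layers = list(list(energy = 180,
                       spots = data.frame(x = 0, y = 0, weight = 1))))), "p")
  z <- seq(1, 240, by = 0.5)
  p0 <- apb_axis_profile(mk(bl0), z = z)
  p75 <- apb_axis_profile(mk(bl75), z = z)
  d0 <- protonqa:::distal_falloff_depth(p0$z, p0$dose, 0.8)
  d75 <- protonqa:::distal_falloff_depth(p75$z, p75$dose, 0.8)
  expect_equal(d0 - d75, 75, tolerance = 1 / 75)
})

test_that("energies outside the machine list fail naming the nearest", {
  bl <- beamline_config()
  expect_error(bragg_idd(260, beamline = bl), "nearest available")
  expect_error(snap_energy(bl, 50), "70")
})

test_that("SOBP optimization hits range and plateau flatness", {
  # layer spacing comparable to the straggling width at this range
  plan <- optimize_sobp(150, 50, 2, field_mm = c(40, 40), layer_spacing_mm = 2)
  d <- attr(plan, "diagnostics")
  expect_lt(abs(d$distal90_mm - 150), 1)
  expect_lt(d$flatness, 0.01)
  # single-layer degenerate request: a pristine peak, no flatness check
  p1 <- optimize_sobp(150, 0, 2, field_mm = c(30, 30))
  expect_equal(attr(p1, "diagnostics")$n_layers, 1L)
})

test_that("SOBP flatness degrades as the layer stack is thinned", {
  flat <- vapply(c(3, 7, 12), function(sp)
    attr(optimize_sobp(150, 50, 2, field_mm = c(30, 30),
                       layer_spacing_mm = sp), "diagnostics")$flatness, 0)
  expect_true(all(diff(flat) > 0))
})

test_that("uniform plans cover the target and react to the override", {
  ph <- build_neck_analog(neck_analog_config(spacing = 2))
  bl <- beamline_config(range_shifter_wet = 75)
  sz <- protonqa:::find_sw_surface(ph)
  box <- list(x = c(-12, 12), y = c(-14, 14), z = sz + c(10, 20))
  plan <- create_uniform_plan(ph, box, bl, label = "F1")
  d <- attr(plan, "diagnostics")
  # optimized (override) target dose uniform within tolerance
  expect_lt(d$max_dev, 0.05)
  # override removed: recomputed dose in the target becomes nonuniform
  cube <- compute_dose_apb(plan, ph)
  ax <- protonqa:::cube_axes(cube)
  sel <- lapply(1:3, function(a) which(ax[[a]] >= box[[a]][1] & ax[[a]] <= box[[a]][2]))
  dose <- cube$dose[sel[[1]], sel[[2]], sel[[3]]]
  expect_gt(max(dose) / min(dose), 1.10)
  expect_error(create_uniform_plan(ph, list(x = c(-100, 100), y = c(0, 10),
                                            z = sz + c(10, 20)), bl),
               "outside the phantom")
})

test_that("spot lattices span the drawn target volume plus margin", {
  ph <- build_slab_phantom(list(list("solid_water", 120)),
                           lateral_size = c(120, 140), spacing = 2)
  bl <- beamline_config(range_shifter_wet = 75)
  # the 1 x 5 x 7 cm target drawn in the solid water stack
  plan <- create_uniform_plan(ph, list(x = c(-25, 25), y = c(-35, 35),
                                       z = c(20, 30)), bl)
  sm <- protonqa:::plan_spot_matrix(plan)
  expect_lte(min(sm[, "x"]), -25)
  expect_gte(max(sm[, "x"]), 25)
  expect_lte(min(sm[, "y"]), -35)
  expect_gte(max(sm[, "y"]), 35)
})

test_that("degrade_plan removes the requested fraction reproducibly", {
  spots <- expand.grid(x = seq(-18, 18, by = 4), y = seq(-18, 18, by = 4))
  spots$weight <- 1
  layers <- lapply(seq(100, 135, by = 5), function(E)
    list(energy = E, spots = spots))
  plan <- pbs_plan(list(list(direction = c(0, 0, 1),
                             beamline = beamline_config(), layers = layers)),
                   "base")
  n0 <- n_spots(plan)
  d1 <- degrade_plan(plan, "spots", 0.3, seed = 5)
  expect_equal(n_spots(d1), n0 - ceiling(0.3 * n0))
  d2 <- degrade_plan(plan, "spots", 0.3, seed = 5)
  expect_identical(protonqa:::plan_spot_matrix(d1),
                   protonqa:::plan_spot_matrix(d2))
  d3 <- degrade_plan(plan, "spots", 0.3, seed = 6)
  expect_false(identical(protonqa:::plan_spot_matrix(d1),
                         protonqa:::plan_spot_matrix(d3)))

  dl <- degrade_plan(plan, "layers", 0.5, seed = 1)
  expect_equal(length(dl$beams[[1]]$layers), 4L)
  for (l in dl$beams[[1]]$layers) expect_equal(nrow(l$spots), nrow(spots))

  expect_identical(n_spots(degrade_plan(plan, "spots", 0)), n0)
  expect_error(degrade_plan(plan, "layers", 0.99), "empty")
})

test_that("plans round-trip through JSON", {
  plan <- optimize_sobp(120, 30, 2, field_mm = c(30, 30))
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)
  back <- read_plan(f)
  expect_equal(back$label, plan$label)
  expect_equal(protonqa:::plan_spot_matrix(back),
               protonqa:::plan_spot_matrix(plan), tolerance = 1e-12)
  expect_equal(back$beams[[1]]$beamline$range_shifter_wet,
               plan$beams[[1]]$beamline$range_shifter_wet)
})
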