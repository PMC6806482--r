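# Materials, phantom builders and water-equivalent-depth raytracing

test_that("slab phantoms fill layer by layer with dominant occupancy", {
  ph <- build_slab_phantom(list(list("water", 300)), lateral_size = 20,
                           spacing = 2)
  expect_equal(ph$dims[3], 150L)
  expect_true(all(ph$materials$name[ph$material_index] == "water"))

  ph2 <- build_slab_phantom(list(list("water", 50), list("bone", 20),
                                 list("water", 50)),
                            lateral_size = 10, spacing = 1)
  counts <- table(ph2$materials$name[ph2$material_index[1, 1, ]])
  expect_equal(unname(counts[["bone"]]), 20L)
  expect_equal(unname(counts[["water"]]), 100L)

  expect_warning(build_slab_phantom(list(list("water", 10.7)), 10, 2),
                 "dominant occupancy")
  expect_error(build_slab_phantom(list(list("kryptonite", 10)), 10, 2),
               "unknown material")
})

test_that("material invariants hold in the default table", {
  m <- default_materials()
  expect_equal(m$rsp[m$name == "water"], 1)
  expect_equal(m$rsp[m$name == "solid_water"], 1.03)
  expect_lte(m$mass_density[m$name == "air"], 0.0013)
  expect_true(all(m$mass_density > 0))
})

test_that("WED raytracing reproduces hand-summed water-equivalent depths", {
  ph <- build_slab_phantom(list(list("water", 150)), 40, 1)
  expect_equal(as.numeric(wed_along_ray(ph, c(0, 0, 0), c(0, 0, 1), 100)),
               100, tolerance = 1e-9)
  ph_sw <- build_slab_phantom(list(list("solid_water", 150)), 40, 1)
  expect_equal(as.numeric(wed_along_ray(ph_sw, c(0, 0, 0), c(0, 0, 1), 100)),
               103, tolerance = 1e-9)
  # 10 mm of solid water has WET 10.3 mm
  expect_equal(as.numeric(wed_along_ray(ph_sw, c(0, 0, 0), c(0, 0, 1), 10)),
               10.3, tolerance = 1e-9)
  ph_mix <- build_slab_phantom(list(list("bone", 20), list("water", 130)), 40, 1)
  expect_equal(as.numeric(wed_along_ray(ph_mix, c(0, 0, 0), c(0, 0, 1), 100)),
               20 * 1.60 + 80, tolerance = 1e-9)
})

test_that("WED is additive along a ray and flags misses", {
  ph <- build_neck_analog(neck_analog_config(spacing = 2))
  set.seed(7)
  for (i in 1:20) {
    p0 <- c(runif(1, -20, 20), runif(1, -30, 30), 0)
    dir <- c(runif(1, -0.2, 0.2), runif(1, -0.2, 0.2), 1)
    dir <- dir / sqrt(sum(dir^2))
    a <- runif(1, 10, 40); b <- a + runif(1, 10, 40)
    w_ab <- as.numeric(wed_along_ray(ph, p0 + a * dir, dir, b - a))
    w_a <- as.numeric(wed_along_ray(ph, p0, dir, a))
    w_b <- as.numeric(wed_along_ray(ph, p0, dir, b))
    expect_equal(w_a + w_ab, w_b, tolerance = 1e-9)
  }
  miss <- wed_along_ray(ph, c(1000, 0, 0), c(0, 0, 1), 50)
  expect_equal(as.numeric(miss), 0)
  expect_false(attr(miss, "hit"))
})

test_that("WED is stable under voxel-grid refinement", {
  # rays through smooth regions; millimeter-scale structures (the air
  # cavity) are inherently voxelization-limited and are excluded
  cfg <- neck_analog_config()
  ph1 <- build_neck_analog(modifyList(cfg, list(spacing = 2)))
  ph2 <- build_neck_analog(modifyList(cfg, list(spacing = 1)))
  for (y in c(-20, -12, 15)) {
    w1 <- as.numeric(wed_along_ray(ph1, c(0, y, 0), c(0, 0, 1), 100))
    w2 <- as.numeric(wed_along_ray(ph2, c(0, y, 0), c(0, 0, 1), 100))
    expect_lt(abs(w1 - w2) / w2, 0.005)
  }
  ph3 <- build_slab_phantom(list(list("solid_water", 30), list("water", 90)),
                            20, 2)
  ph4 <- build_slab_phantom(list(list("solid_water", 30), list("water", 90)),
                            20, 1)
  w3 <- as.numeric(wed_along_ray(ph3, c(0, 0, 0), c(0.1, 0.05, 1), 100))
  w4 <- as.numeric(wed_along_ray(ph4, c(0, 0, 0), c(0.1, 0.05, 1), 100))
  expect_lt(abs(w3 - w4) / w4, 0.005)
})

test_that("phantom builders are deterministic", {
  a <- build_neck_analog(neck_analog_config(spacing = 2))
  b <- build_neck_analog(neck_analog_config(spacing = 2))
  expect_identical(a$material_index, b$material_index)
})

test_that("neck analog geometry matches its analytic cross sections", {
  # half-millimeter voxels resolve the few-mm structures to the 2% level
  cfg <- neck_analog_config(spacing = 0.5, lateral_size = c(30, 90),
                            downstream_sw = 10)
  ph <- build_neck_analog(cfg)
  nm <- ph$materials$name[ph$material_index[1, , ]] # one x-slice, [y, z]
  vox_area <- prod(ph$spacing[2:3])
  n_air_cavity <- sum(nm == "air" &
                        as.logical(outer(seq_len(ph$dims[2]), seq_len(ph$dims[3]),
                                         function(j, k) {
                                           y <- ph$origin[2] + (j - 1) * ph$spacing[2]
                                           z <- ph$origin[3] + (k - 1) * ph$spacing[3]
                                           (y - cfg$structure_offset[1])^2 +
                                             (z - cfg$tissue_radius - cfg$structure_offset[2])^2 <
                                             (cfg$bone_r_inner + 2)^2
                                         })))
  n_bone <- sum(nm == "bone")
  expect_equal(n_air_cavity * vox_area, pi * cfg$air_radius^2, tolerance = 0.02)
  expect_equal(n_bone * vox_area, pi * (cfg$bone_r_outer^2 - cfg$bone_r_inner^2),
               tolerance = 0.02)

  # a ray through the air cavity has smaller WED than one through solid bone
  w_air <- as.numeric(wed_along_ray(ph, c(0, 0, 0), c(0, 0, 1), 60))
  w_bone <- as.numeric(wed_along_ray(ph, c(0, cfg$bone_r_inner + 2, 0),
                                     c(0, 0, 1), 60))
  expect_lt(w_air, w_bone)

  # degenerate configuration: no air cavity
  ph0 <- build_neck_analog(neck_analog_config(air_radius = 0, spacing = 2))
  nm0 <- ph0$materials$name[ph0$material_index[1, , ]]
  ys <- ph0$origin[2] + (seq_len(ph0$dims[2]) - 1) * ph0$spacing[2]
  zs <- ph0$origin[3] + (seq_len(ph0$dims[3]) - 1) * ph0$spacing[3]
  incyl <- outer(ys, zs, function(y, z) sqrt(y^2 + (z - 35)^2) < 30)
  expect_false(any(nm0[incyl] == "air"))
  expect_true(any(nm0 == "bone"))
  expect_error(build_neck_analog(neck_analog_config(air_radius = 10)),
               "nested")
})

test_that("HU calibration interpolates between its anchors", {
  expect_equal(hu_to_material(0)$name, "water")
  expect_equal(hu_to_material(-1000)$name, "air")
  m500 <- hu_to_material(500)
  # linear interpolation between the water (0) and bone (1500) anchors
  expect_equal(m500$mass_density, 1 + 500 / 1500 * 0.85, tolerance = 1e-9)
  expect_equal(m500$rsp, 1 + 500 / 1500 * 0.60, tolerance = 1e-9)
  expect_warning(m <- hu_to_material(5000), "clamped")
  # density monotone nondecreasing in HU
  hu <- seq(-1000, 3000, by = 250)
  dens <- vapply(hu, function(h) hu_to_material(h)$mass_density, 0)
  expect_true(all(diff(dens) >= 0))
})

test_that("materials round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_materials(default_materials(), f)
  m <- read_materials(f)
  expect_equal(m$rsp, default_materials()$rsp)
  expect_equal(m$name, default_materials()$name)
})

test_that("HU volumes import as quantized-material phantoms", {
  set.seed(3)
  hu <- array(round(runif(4 * 4 * 10, -50, 50)), c(4, 4, 10))
  hu[, , 5] <- 1200 # a bone-like slab
  ph <- phantom_from_hu(hu, spacing = 2, bin_width = 50)
  expect_s3_class(ph, "voxel_phantom")
  expect_equal(ph$dims, dim(hu))
  # the bone-like bin carries an interpolated density above water
  dens <- ph$materials$mass_density[ph$material_index[, , 5]]
  expect_true(all(dens > 1.5))
  w <- as.numeric(wed_along_ray(ph, c(0.1, 0.1, 0), c(0, 0, 1), 20))
  expect_gt(w, 15)
})
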