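# Per-step physics of the Monte Carlo engine: stopping power, multiple
# scattering, straggling and nuclear interaction sampling

test_that("the stopping-power model matches its range-energy derivative", {
  # oracle: S = E^(1-p) / (10 alpha p), about 0.54 MeV/mm at 150 MeV
  expect_equal(stopping_power(150), 0.54, tolerance = 0.03)
  E <- seq(70, 230, by = 5)
  expect_true(all(diff(stopping_power(E)) < 0))
  sw <- default_materials()
  sw <- sw[sw$name == "solid_water", ]
  expect_equal(stopping_power(100, sw), 1.03 * stopping_power(100),
               tolerance = 1e-12)
  expect_error(stopping_power(-5), "positive")
})

test_that("scattering sampling reproduces the Highland formula", {
  expect_equal(sample_scattering_angle(150, 0, n = 10)[, 1], rep(0, 10))
  th <- sample_scattering_angle(150, 10, n = 1e5, seed = 4)
  # closed-form Highland oracle at 150 MeV, 10 mm water
  mp <- 938.272
  pv <- ((150 + mp)^2 - mp^2) / (150 + mp)
  x_rel <- 10 / 360.8
  th0 <- 14.1 / pv * sqrt(x_rel) * (1 + log10(x_rel) / 9)
  expect_equal(sd(th[, 1]), th0, tolerance = 0.02)
  expect_equal(sd(th[, 2]), th0, tolerance = 0.02)

  # splitting a 10-mm step into ten 1-mm sub-steps conserves the variance
  acc <- 0
  for (i in 0:9) {
    s <- sample_scattering_angle(150, 1, cum_wet = i, n = 4e4, seed = 40 + i)
    acc <- acc + var(s[, 1])
  }
  expect_equal(acc, th0^2, tolerance = 0.05)
})

test_that("energy-loss straggling has the Bohr variance", {
  expect_equal(sample_energy_straggling(0, 0, n = 5), rep(0, 5))
  x <- sample_energy_straggling(5, 10, rsp = 1, kinetic_energy = 150,
                                n = 1e5, seed = 9)
  expect_equal(var(x), 0.0087 * 10, tolerance = 0.03)
  expect_equal(mean(x), 5, tolerance = 0.01)
  # truncation: losses stay within [0, E]
  y <- sample_energy_straggling(1, 40, rsp = 1, kinetic_energy = 1.5,
                                n = 1e4, seed = 2)
  expect_true(all(y >= 0 & y <= 1.5))
})

test_that("nuclear interaction sampling follows the tabulated cross section", {
  p_hat <- mean(sample_nuclear_interaction(150, 1, n = 1e6, seed = 3))
  sigma <- protonqa:::nuclear_sigma(150)
  p_true <- 1 - exp(-sigma * 1)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e6))
  # below the threshold energy nothing interacts
  expect_equal(sum(sample_nuclear_interaction(5, 10, n = 1e6, seed = 3)), 0L)
})

test_that("full-range transport shows ~1.1% range straggling", {
  mc <- fx_pencil_mc()
  zc <- protonqa:::cube_axes(mc)[[3]]
  ddz <- apply(mc$dose, 3, sum)
  d80 <- protonqa:::distal_falloff_depth(zc, ddz, 0.8)
  d20 <- protonqa:::distal_falloff_depth(zc, ddz, 0.2)
  sig_est <- (d20 - d80) / 1.683
  r0 <- proton_range(150)
  expect_gt(sig_est / r0, 0.008)
  expect_lt(sig_est / r0, 0.014)
})
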