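# Virtual planar detector and OPG-style ASCII round trip

make_cube <- function() {
  # smooth analytic cube: quadratic lateral falloff, linear depth ramp
  nx <- 41; nz <- 60
  ax <- seq(-40, 40, by = 2)
  zs <- seq(1, 119, by = 2)
  dose <- array(0, c(nx, nx, nz))
  for (k in seq_len(nz))
    dose[, , k] <- outer(ax, ax, function(x, y)
      (1 + 0.004 * zs[k]) * exp(-(x^2 + y^2) / 900))
  dose_cube(dose, c(2, 2, 2), c(-40, -40, 1), engine = "apb",
            meta = list(surface_z = 0))
}

test_that("noise-free measurement equals trilinear sampling with d_m bookkeeping", {
  cube <- make_cube()
  m <- simulate_measurement(cube, stack_mm = 1.94, surface_z = 0, n_det = 5,
                            noise_sigma = 0)
  # a 2-mm-WET solid-water stack puts the plane at the study's shallowest d_m
  expect_equal(m$d_m, 1.94 * 1.03 + 6, tolerance = 1e-12)
  expect_equal(m$pitch, 7)
  direct <- extract_plane(cube, m$z_plane, m$x, m$y)
  expect_equal(m$values, direct, tolerance = 1e-12)

  # moving 10 mm deeper in solid water adds exactly 10.3 mm of d_m
  m2 <- simulate_measurement(cube, stack_mm = 11.94, surface_z = 0, n_det = 5,
                             noise_sigma = 0)
  expect_equal(m2$d_m - m$d_m, 10.3, tolerance = 1e-12)
  expect_error(simulate_measurement(cube, stack_mm = 500, surface_z = 0),
               "outside cube")
})

test_that("measurement noise is unbiased and calibration multiplies", {
  cube <- make_cube()
  clean <- simulate_measurement(cube, 10, surface_z = 0, n_det = 3,
                                noise_sigma = 0)
  acc <- 0
  nseed <- 1200
  for (s in seq_len(nseed))
    acc <- acc + simulate_measurement(cube, 10, surface_z = 0, n_det = 3,
                                      noise_sigma = 0.02, seed = s)$values
  m <- acc / nseed
  z <- (m - clean$values) / (clean$values * 0.02 / sqrt(nseed))
  expect_true(all(abs(z) < 4))

  cal <- simulate_measurement(cube, 10, surface_z = 0, n_det = 3,
                              noise_sigma = 0, calibration_factor = 1.05)
  expect_equal(cal$values, 1.05 * clean$values, tolerance = 1e-12)
})

test_that("OPG planes round-trip and tolerate CRLF", {
  cube <- make_cube()
  m <- simulate_measurement(cube, 8, surface_z = 0, n_det = c(6, 4),
                            noise_sigma = 0.01, seed = 7)
  f <- tempfile(fileext = ".opg")
  write_opg(m, f)
  back <- read_opg(f)
  expect_lt(max(abs(back$values - m$values)), 1e-6)
  expect_equal(back$pitch, m$pitch)
  expect_equal(back$d_m, m$d_m, tolerance = 1e-4)
  expect_equal(back$x, m$x, tolerance = 1e-4)

  crlf <- tempfile(fileext = ".opg")
  writeLines(paste0(readLines(f), "\r"), crlf, sep = "\n")
  back2 <- read_opg(crlf)
  expect_equal(back2$values, back$values)
})

test_that("malformed OPG files fail naming the offending line", {
  cube <- make_cube()
  m <- simulate_measurement(cube, 8, surface_z = 0, n_det = 4, noise_sigma = 0)
  f <- tempfile(fileext = ".opg")
  write_opg(m, f)
  lines <- readLines(f)
  # drop one body row: header row count no longer matches
  bad <- tempfile(fileext = ".opg")
  writeLines(lines[-(length(lines) - 1)], bad)
  expect_error(read_opg(bad), "declares")
  # truncate one row's values
  lines2 <- lines
  body_at <- match("<asciibody>", lines2)
  lines2[body_at + 2] <- sub("\t[^\t]*$", "", lines2[body_at + 2])
  bad2 <- tempfile(fileext = ".opg")
  writeLines(lines2, bad2)
  expect_error(read_opg(bad2), "row 2")
  expect_error(suppressWarnings(read_opg(tempfile())))
})
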