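# Monte Carlo transport: conservation, uncertainty semantics, cross-engine
# consistency

test_that("the energy ledger balances injected, deposited and escaped", {
  rs <- run_stats(fx_pencil_mc())
  expect_lt(abs(rs$deposited_mev + rs$escaped_mev - rs$injected_mev) /
              rs$injected_mev, 0.001)
})

test_that("uncertainty scales as one over root N", {
  ph <- water_slab(180, 60, 2)
  plan <- pencil_plan(140)
  u <- vapply(c(1e5, 2e5), function(N) {
    mc <- mc_transport(plan, ph, stop = list(histories = N), seed = 8)
    median(mc$rel_unc[mc$dose > 0.5 * max(mc$dose)], na.rm = TRUE)
  }, 0)
  expect_equal(u[2] / u[1], 0.707, tolerance = 0.05 / 0.707)
})

test_that("MC dose is invariant under the seed within statistics", {
  ph <- water_slab(180, 60, 2)
  plan <- pencil_plan(140)
  a <- mc_transport(plan, ph, stop = list(histories = 2e5), seed = 1)
  b <- mc_transport(plan, ph, stop = list(histories = 2e5), seed = 99)
  sel <- a$dose > 0.5 * max(a$dose)
  z <- (a$dose[sel] - b$dose[sel]) /
    sqrt((a$dose[sel] * a$rel_unc[sel])^2 + (b$dose[sel] * b$rel_unc[sel])^2)
  # seed change shifts voxels only within their combined statistical error
  expect_lt(mean(abs(z) > 3), 0.01)
})

test_that("doubling all spot weights exactly doubles the MC dose", {
  ph <- water_slab(150, 50, 2)
  plan <- pencil_plan(130)
  plan2 <- plan
  plan2$beams[[1]]$layers[[1]]$spots$weight <- 2
  a <- mc_transport(plan, ph, stop = list(histories = 5e4), seed = 6)
  b <- mc_transport(plan2, ph, stop = list(histories = 5e4), seed = 6)
  expect_equal(b$dose, 2 * a$dose, tolerance = 1e-9)
})

test_that("the uncertainty stopping rule halts at its target", {
  ph <- water_slab(150, 50, 2)
  plan <- pencil_plan(130)
  mc <- mc_transport(plan, ph, stop = list(uncertainty = 0.05), seed = 12,
                     batch_hist = 2e4)
  rs <- run_stats(mc)
  expect_true(rs$reached_target)
  expect_lte(rs$aggregate_unc, 0.05)
  expect_gte(rs$n_batches, 10)
})

test_that("degraded plans never exceed the parent dose field", {
  # nonnegative weights: removing spots can only remove dose (exact in APB)
  ph <- water_slab(150, 80, 2)
  plan <- optimize_sobp(120, 30, 2, field_mm = c(30, 30))
  sub <- degrade_plan(plan, "spots", 0.4, seed = 3)
  c_full <- compute_dose_apb(plan, ph)
  c_sub <- compute_dose_apb(sub, ph)
  expect_true(all(c_sub$dose <= c_full$dose + 1e-12))
})

test_that("MC and APB agree in water at 3%/3mm over a mini SOBP", {
  fx <- fx_mini_sobp()
  ax <- protonqa:::cube_axes(fx$mc)
  pts <- expand.grid(x = ax[[1]][seq(1, length(ax[[1]]), by = 3)],
                     y = ax[[2]][seq(1, length(ax[[2]]), by = 3)],
                     z = ax[[3]][seq(1, length(ax[[3]]), by = 3)])
  # MC voxel values at the lattice points act as the sparse reference
  ii <- match(pts$x, ax[[1]]); jj <- match(pts$y, ax[[2]]); kk <- match(pts$z, ax[[3]])
  pts$dose <- fx$mc$dose[cbind(ii, jj, kk)]
  res <- gamma_3d(pts, fx$apb, gamma_criterion(3, 3, threshold_percent = 10))
  expect_gte(res$pass_rate, 98)
})
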