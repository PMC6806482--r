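# Shared fixtures, computed lazily and cached for the whole test run so the
# expensive Monte Carlo objects are built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

water_slab <- function(depth = 200, lateral = 80, spacing = 2) {
  build_slab_phantom(list(list("water", depth)), lateral_size = lateral,
                     spacing = spacing)
}

pencil_plan <- function(energy = 150, beamline = beamline_config()) {
  pbs_plan(list(list(direction = c(0, 0, 1), beamline = beamline,
                     layers = list(list(energy = energy,
                                        spots = data.frame(x = 0, y = 0,
                                                           weight = 1))))),
           label = "pencil")
}

# small pencil-beam MC run in water reused by the ledger / uncertainty tests
fx_pencil_mc <- function() fixture("pencil_mc", function() {
  mc_transport(pencil_plan(150), water_slab(), stop = list(histories = 2e5),
               seed = 42)
})

# mini SOBP (reduced range/modulation/field) and its two-engine dose cubes,
# reused by the cross-engine consistency tests
fx_mini_sobp <- function() fixture("mini_sobp", function() {
  plan <- optimize_sobp(150, 40, 2, field_mm = c(30, 30))
  ph <- build_slab_phantom(list(list("water", 180)), lateral_size = 100,
                           spacing = 2)
  apb <- compute_dose_apb(plan, ph)
  mc <- mc_transport(plan, ph, stop = list(histories = 6e6), seed = 3,
                     open_step_mm = 12)
  list(plan = plan, phantom = ph, apb = apb, mc = mc)
})

# scaled-down neck experiment bundle shared by the acceptance tests
fx_neck <- function() fixture("neck", function() {
  cfg <- neck_experiment_config(seed = 20)
  run_validation(cfg, keep_cubes = TRUE, verbose = FALSE)
})
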