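#' Configuration of the synthetic neck validation experiment
#'
#' The study conditions: a tuned neck analog (bone annulus with an air
#' cavity, chosen so the analytical engine's infinite-slab artifact reaches
#' the >= 20% regime distal to the bone-air interface), a 75-mm-WET range
#' shifter with a 20-mm air gap, two uniform-optimized plans (F1, F3) plus
#' their randomly degraded copies (F2: spots removed, F4: layers removed),
#' virtual detector planes at the standard measurement depths, 1% channel
#' noise, and the 2%/2, 3%/3 and 5%/3 gamma criteria.
#'
#' Lateral target sizes and Monte Carlo uncertainty targets are desk-scale
#' choices (see the methods vignette); measurement depths, detector pitch
#' and buildup, noise level and gamma criteria follow the study design.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param eval_unc,source_unc MC relative-uncertainty targets for the
#'   evaluated cubes and for the high-statistics measurement-source cube.
#' @return config list for [run_validation()].
#' @export
neck_experiment_config <- function(seed = 1, eval_unc = 0.04,
                                   source_unc = 0.025) {
  list(
    label = "neck",
    seed = seed,
    phantom = neck_analog_config(),
    beamline = beamline_config(range_shifter_wet = 75, air_gap = 20),
    grid_spacing = 1,
    plans = list(
      F1 = list(type = "uniform", angle = 0,
                box = list(x = c(-10, 10), y = c(-12, 12), z_rel = c(10, 20))),
      F2 = list(type = "degrade", parent = "F1", mode = "spots", fraction = 0.3),
      F3 = list(type = "uniform", angle = 0,
                box = list(x = c(-10, 10), y = c(-4, 20), z_rel = c(16, 26))),
      F4 = list(type = "degrade", parent = "F3", mode = "layers", fraction = 0.5)),
    depths = list(F1 = c(8, 26), F2 = c(8, 26), F3 = c(8, 35), F4 = c(8, 26)),
    measurement = list(pitch = 7, n_det = 7, noise_sigma = 0.01,
                       calibration_factor = 1, buildup_wet = 6),
    mc = list(eval_unc = eval_unc, source_unc = source_unc,
              source_spacing = 2, batch_hist = 400000, max_batches = 4000),
    gamma = list(criteria = list(c(2, 2), c(3, 3), c(5, 3)),
                 threshold_2d = 5, threshold_3d = 10),
    depth_search = list(window = 5, step = 0.1, criterion = c(3, 3)),
    discrepancy_region = list(x = c(-8, 8), y = c(-8, 8), z_rel = c(4, 20)))
}

# first solid-water voxel depth along the (x, y) column: the measurement
# surface in beam-eye-view coordinates
find_sw_surface <- function(phantom, x = 0, y = 0) {
  lo <- phantom$origin - phantom$spacing / 2
  i <- pmin(pmax(floor((x - lo[1]) / phantom$spacing[1]), 0), phantom$dims[1] - 1) + 1
  j <- pmin(pmax(floor((y - lo[2]) / phantom$spacing[2]), 0), phantom$dims[2] - 1) + 1
  col <- phantom$material_index[i, j, ]
  k <- which(phantom$materials$name[col] == "solid_water")[1]
  if (is.na(k)) stop("no solid water along this column")
  lo[3] + (k - 1) * phantom$spacing[3]
}

# build the configured phantom (neck analog, or the water-breast analog)
build_experiment_phantom <- function(pcfg) {
  if (inherits(pcfg, "neck_config")) return(build_neck_analog(pcfg))
  if (identical(pcfg$type, "breast"))
    return(build_breast_analog(radius = pcfg$radius,
                               slab_thickness = pcfg$slab_thickness,
                               lateral_size = pcfg$lateral_size,
                               spacing = pcfg$spacing))
  stop("unknown phantom configuration")
}

# beam-eye-view phantom for a plan (oblique incidence rotates the phantom)
plan_bev_phantom <- function(config, phantom, nm) {
  pc <- config$plans[[nm]]
  while (!is.null(pc$parent)) pc <- config$plans[[pc$parent]]
  ang <- if (is.null(pc$angle)) 0 else pc$angle
  rotate_phantom(phantom, ang)
}

# build the plan set described by a config (on the optimization phantom,
# heterogeneity override active, each beam in its own beam-eye-view)
build_config_plans <- function(config, phantom, physics = default_physics()) {
  plans <- list()
  for (nm in names(config$plans)) {
    pc <- config$plans[[nm]]
    if (pc$type == "uniform") {
      bev <- plan_bev_phantom(config, phantom, nm)
      sz <- find_sw_surface(bev)
      box <- list(x = pc$box$x, y = pc$box$y, z = sz + pc$box$z_rel)
      plans[[nm]] <- create_uniform_plan(bev, box, config$beamline,
                                         margin_sigma = 1.0, label = nm,
                                         physics = physics)
    } else {
      plans[[nm]] <- degrade_plan(plans[[pc$parent]], pc$mode, pc$fraction,
                                  seed = config$seed + 7 + match(nm, names(config$plans)))
      plans[[nm]]$label <- nm
    }
  }
  plans
}

#' Configuration of the synthetic breast validation experiment
#'
#' The water-breast analog (45-mm hemisphere on solid-water slabs) with an
#' en-face and a 30-degree oblique beam, each optimized for a target volume
#' crossing from the dome into the solid water, measured at the standard
#' breast depths (8 and 13 mm).
#'
#' @inheritParams neck_experiment_config
#' @return config list for [run_validation()].
#' @export
breast_experiment_config <- function(seed = 1, eval_unc = 0.04,
                                     source_unc = 0.025) {
  cfg <- neck_experiment_config(seed, eval_unc, source_unc)
  cfg$label <- "breast"
  cfg$phantom <- list(type = "breast", radius = 45, slab_thickness = 50,
                      lateral_size = c(110, 110), spacing = 1)
  cfg$plans <- list(
    enface = list(type = "uniform", angle = 0,
                  box = list(x = c(-10, 10), y = c(-10, 10),
                             z_rel = c(-10, 12))),
    oblique = list(type = "uniform", angle = 30,
                   box = list(x = c(-10, 10), y = c(-10, 10),
                              z_rel = c(-10, 12))))
  cfg$depths <- list(enface = c(8, 13), oblique = c(8, 13))
  cfg$discrepancy_region <- NULL
  cfg
}

#' Run the full synthetic validation experiment
#'
#' Builds the phantom, constructs the plan set (uniform plans optimized on
#' the heterogeneity-overridden phantom, then recalculated on the true
#' phantom; degraded copies by seeded random removal), computes APB and MC
#' dose cubes, generates virtual detector measurements at the configured
#' depths from an independent high-statistics MC cube with channel noise,
#' runs the 2D depth-of-best-agreement search and the 2D/3D gamma analyses
#' for both engines at every criterion, and collects everything into a
#' tabular report.
#'
#' @param config a [neck_experiment_config()]-style list.
#' @param outdir optional output directory (report.csv, report.md, OPG
#'   planes).
#' @param keep_cubes return the dose cubes alongside the report.
#' @param verbose print stage progress.
#' @param physics a [proton_physics()] object.
#' @return object of class `validation_report`: `table` (one row per
#'   engine/plan/plane), `averages` (per engine), plus the phantom, plans
#'   and (optionally) cubes.
#' @export
run_validation <- function(config, outdir = NULL, keep_cubes = TRUE,
                           verbose = interactive(), physics = default_physics()) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  say("[phantom] building %s analog", config$label)
  ph <- stage("phantom", build_experiment_phantom(config$phantom))
  say("[plans] optimizing on override phantom")
  plans <- stage("plans", build_config_plans(config, ph, physics))

  cubes <- list()
  rows <- list()
  crits2 <- lapply(config$gamma$criteria, function(cd)
    gamma_criterion(cd[1], cd[2], config$gamma$threshold_2d))
  crits3 <- lapply(config$gamma$criteria, function(cd)
    gamma_criterion(cd[1], cd[2], config$gamma$threshold_3d))
  dsc <- config$depth_search$criterion
  ds_crit <- gamma_criterion(dsc[1], dsc[2], config$gamma$threshold_2d)

  for (nm in names(plans)) {
    pl <- plans[[nm]]
    k <- match(nm, names(plans))
    ph_bev <- plan_bev_phantom(config, ph, nm)
    sz <- find_sw_surface(ph_bev)
    say("[dose %s] APB", nm)
    apb <- stage(paste0("apb_", nm),
                 compute_dose_apb(pl, ph_bev, config$grid_spacing, physics = physics))
    say("[dose %s] MC evaluation cube", nm)
    mc <- stage(paste0("mc_", nm),
                mc_transport(pl, ph_bev, config$grid_spacing,
                             stop = list(uncertainty = config$mc$eval_unc),
                             seed = config$seed + 100 + k,
                             batch_hist = config$mc$batch_hist,
                             max_batches = config$mc$max_batches,
                             physics = physics))
    say("[dose %s] MC measurement-source cube", nm)
    src_sp <- if (is.null(config$mc$source_spacing)) config$grid_spacing else
      config$mc$source_spacing
    src <- stage(paste0("mc_source_", nm),
                 mc_transport(pl, ph_bev, src_sp,
                              stop = list(uncertainty = config$mc$source_unc),
                              seed = config$seed + 200 + k,
                              batch_hist = config$mc$batch_hist,
                              max_batches = config$mc$max_batches,
                              physics = physics))
    apb$meta$surface_z <- mc$meta$surface_z <- src$meta$surface_z <- sz
    if (keep_cubes) cubes[[nm]] <- list(apb = apb, mc = mc, source = src)

    for (d_m in config$depths[[nm]]) {
      stack_mm <- (d_m - config$measurement$buildup_wet) / 1.03
      meas <- stage(paste0("measure_", nm),
                    simulate_measurement(src, stack_mm, surface_z = sz,
                                         pitch = config$measurement$pitch,
                                         n_det = config$measurement$n_det,
                                         buildup_wet = config$measurement$buildup_wet,
                                         calibration_factor = config$measurement$calibration_factor,
                                         noise_sigma = config$measurement$noise_sigma,
                                         seed = config$seed + 300 + 10 * k + round(d_m)))
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        write_opg(meas, file.path(outdir, sprintf("%s_dm%02.0f.opg", nm, d_m)))
      }
      for (eng in c("apb", "mc")) {
        cube <- if (eng == "apb") apb else mc
        say("[gamma %s %s] d_m = %.0f mm", nm, eng, d_m)
        ds <- stage("depth_search",
                    depth_search(meas, cube, ds_crit,
                                 window = config$depth_search$window,
                                 step = config$depth_search$step))
        zf <- cube_z_front(cube)
        margin <- 3 * max(vapply(crits2, function(cr) cr$dta_mm, 0))
        ref <- interp_plane_to_grid(meas, 2)
        ex <- seq(min(ref$x) - margin, max(ref$x) + margin, by = 2)
        ey <- seq(min(ref$y) - margin, max(ref$y) + margin, by = 2)
        ev <- list(values = extract_plane(cube, zf + ds$d_gamma, ex, ey),
                   x = ex, y = ey)
        g2 <- vapply(crits2, function(cr) gamma_2d(ref, ev, cr)$pass_rate, 0)
        pts <- expand.grid(x = meas$x, y = meas$y)
        pts$z <- meas$z_plane
        pts$dose <- as.numeric(meas$values)
        g3 <- vapply(crits3, function(cr)
          tryCatch(suppressWarnings(gamma_3d(pts, cube, cr)$pass_rate),
                   error = function(e) NA_real_), 0)
        rows[[length(rows) + 1]] <- data.frame(
          engine = toupper(eng), plan = nm, d_m = d_m, d_e = ds$d_e,
          d_gamma = ds$d_gamma, delta = ds$delta,
          g2d_2_2 = g2[1], g2d_3_3 = g2[2], g2d_5_3 = g2[3],
          g3d_2_2 = g3[1], g3d_3_3 = g3[2], g3d_5_3 = g3[3])
      }
    }
  }
  tab <- do.call(rbind, rows)
  num <- c("delta", "g2d_2_2", "g2d_3_3", "g2d_5_3", "g3d_2_2", "g3d_3_3",
           "g3d_5_3")
  avg <- do.call(rbind, lapply(split(tab, tab$engine), function(d) {
    out <- data.frame(engine = d$engine[1], n_planes = nrow(d),
                      mean_abs_delta = mean(abs(d$delta)))
    for (cn in num[-1]) out[[cn]] <- mean(d[[cn]], na.rm = TRUE)
    out
  }))
  rownames(avg) <- NULL
  rep <- structure(list(table = tab, averages = avg, config = config,
                        phantom = ph, plans = plans,
                        cubes = if (keep_cubes) cubes else NULL),
                   class = "validation_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_report_csv(rep, file.path(outdir, "report.csv"))
    write_report_md(rep, file.path(outdir, "report.md"))
  }
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation report '%s': %d rows\n", x$config$label,
              nrow(x$table)))
  print(x$table, digits = 4, row.names = FALSE)
  cat("\nper-engine averages:\n")
  print(x$averages, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as CSV / Markdown
#' @param report a `validation_report`.
#' @param path output path.
#' @export
write_report_csv <- function(report, path) {
  fmt <- report$table
  for (cn in names(fmt)) if (is.numeric(fmt[[cn]])) fmt[[cn]] <- sprintf("%.4f", fmt[[cn]])
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_md <- function(report, path) {
  t <- report$table
  hdr <- c("engine", "plan", "d_m", "d_e", "d_gamma", "d_e-d_gamma",
           "2D 2%/2mm", "2D 3%/3mm", "2D 5%/3mm",
           "3D 2%/2mm", "3D 3%/3mm", "3D 5%/3mm")
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (i in seq_len(nrow(t)))
    lines <- c(lines, paste0("| ", t$engine[i], " | ", t$plan[i], " | ",
                             paste(sprintf("%.1f", as.numeric(t[i, 3:12])),
                                   collapse = " | "), " |"))
  writeLines(lines, path)
  invisible(path)
}

#' Voxelwise engine comparison in a region
#'
#' Relative APB-versus-MC dose difference map normalized to the MC
#' maximum, summarized (max and 95th percentile, in %) over a named
#' region; used to quantify the infinite-slab artifact distal to discrete
#' heterogeneities.
#'
#' @param apb_cube,mc_cube [dose_cube()]s on identical grids.
#' @param region list with `x`, `y`, `z` two-vectors (mm); NULL = whole grid.
#' @return list with `max_pct`, `p95_pct`, `n_voxels`.
#' @export
compare_engines <- function(apb_cube, mc_cube, region = NULL) {
  if (!isTRUE(all.equal(apb_cube$dims, mc_cube$dims)) ||
      !isTRUE(all.equal(apb_cube$spacing, mc_cube$spacing)) ||
      !isTRUE(all.equal(apb_cube$origin, mc_cube$origin)))
    stop("cubes are on different grids")
  ax <- cube_axes(mc_cube)
  sel <- array(TRUE, mc_cube$dims)
  if (!is.null(region)) {
    for (a in 1:3) {
      r <- region[[c("x", "y", "z")[a]]]
      if (!is.null(r)) {
        keep <- ax[[a]] >= r[1] & ax[[a]] <= r[2]
        sel <- sweep(sel, a, keep, "&")
      }
    }
  }
  dmax <- max(mc_cube$dose)
  diff <- abs(apb_cube$dose[sel] - mc_cube$dose[sel]) / dmax * 100
  list(max_pct = max(diff),
       p95_pct = as.numeric(quantile(diff, 0.95)),
       n_voxels = sum(sel))
}

#' Replace a phantom by its homogeneous-water counterpart
#'
#' Control condition for engine comparisons: the same grid with every
#' voxel set to water.
#'
#' @param phantom a [voxel_phantom()].
#' @return a [voxel_phantom()].
#' @export
water_counterpart <- function(phantom) {
  iw <- material_row(phantom$materials, "water")
  phantom$material_index[] <- iw
  phantom$masks <- list()
  phantom
}
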