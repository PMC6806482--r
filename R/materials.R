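#' Define a material
#'
#' A material is summarized by its mass density, relative (linear) stopping
#' power versus water, radiation length, mean ionization energy and a
#' multiplier on water's macroscopic nonelastic nuclear cross section.
#'
#' @param name material name.
#' @param mass_density g/cm^3; must be positive (air is the exception with
#'   density at or below 0.0013).
#' @param rsp relative stopping power versus water (water-equivalent
#'   thickness per unit physical thickness).
#' @param radiation_length g/cm^2.
#' @param mean_ionization_energy eV.
#' @param nuclear_scale multiplier on water's macroscopic nonelastic cross
#'   section; defaults to `rsp` (both scale roughly with electron density).
#' @return A one-row data frame of class `material_spec`.
#' @export
material_spec <- function(name, mass_density, rsp, radiation_length,
                          mean_ionization_energy, nuclear_scale = rsp) {
  stopifnot(is.character(name), mass_density > 0, rsp >= 0,
            radiation_length > 0, mean_ionization_energy > 0,
            nuclear_scale >= 0)
  if (grepl("^air", name) && mass_density > 0.0013)
    stop("air must have mass_density <= 0.0013 g/cm^3")
  out <- data.frame(name = name, mass_density = mass_density, rsp = rsp,
                    radiation_length = radiation_length,
                    mean_ionization_energy = mean_ionization_energy,
                    nuclear_scale = nuclear_scale,
                    stringsAsFactors = FALSE)
  class(out) <- c("material_spec", class(out))
  out
}

#' Default material table
#'
#' Water has rsp exactly 1; the solid-water phantom material has rsp 1.03
#' (its water-equivalent thickness ratio). Cortical bone defaults to density
#' 1.85 g/cm^3 and rsp 1.60; all values are overridable via a YAML materials
#' file ([read_materials()]).
#'
#' @return data frame of material specs, one row per material.
#' @export
default_materials <- function() {
  m <- rbind(
    material_spec("air",         0.0012, 0.0011, 36.62, 85.7),
    material_spec("water",       1.000,  1.00,   36.08, 75.0),
    material_spec("solid_water", 1.045,  1.03,   36.50, 75.3),
    material_spec("soft_tissue", 1.040,  1.04,   36.20, 74.7),
    material_spec("bone",        1.850,  1.60,   16.60, 112.0)
  )
  class(m) <- c("material_table", "data.frame")
  m
}

# per-material helper vectors (x0 in mm) aligned with the table rows
material_vectors <- function(materials) {
  list(rsp = materials$rsp,
       density = materials$mass_density,
       x0_mm = materials$radiation_length / materials$mass_density * 10,
       nuc = materials$nuclear_scale)
}

material_row <- function(materials, name) {
  i <- match(name, materials$name)
  if (is.na(i)) stop(sprintf("unknown material '%s'", name))
  i
}

#' Read / write a materials table as YAML
#'
#' The file is keyed by material name, each entry carrying the five
#' [material_spec()] fields.
#'
#' @param path file path.
#' @param materials a material table (for writing).
#' @return [read_materials()] returns a material table.
#' @export
read_materials <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y), function(nm) {
    f <- y[[nm]]
    material_spec(nm, f$mass_density, f$rsp, f$radiation_length,
                  f$mean_ionization_energy,
                  if (is.null(f$nuclear_scale)) f$rsp else f$nuclear_scale)
  })
  m <- do.call(rbind, rows)
  class(m) <- c("material_table", "data.frame")
  m
}

#' @rdname read_materials
#' @export
write_materials <- function(materials, path) {
  y <- lapply(seq_len(nrow(materials)), function(i) {
    as.list(materials[i, c("mass_density", "rsp", "radiation_length",
                           "mean_ionization_energy", "nuclear_scale")])
  })
  names(y) <- materials$name
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Map a Hounsfield value to a material
#'
#' Three-segment piecewise-linear calibration anchored at air (-1000),
#' water (0) and cortical bone (1500), extended linearly to 3000; density
#' and rsp are monotone nondecreasing in HU. Values outside [-1024, 3000]
#' are clamped with a warning.
#'
#' @param hu Hounsfield value (scalar).
#' @return A `material_spec` for the interpolated material (named
#'   `hu_<value>`; exact anchor hits return the canonical material).
#' @export
hu_to_material <- function(hu) {
  stopifnot(length(hu) == 1, is.finite(hu))
  if (hu < -1024 || hu > 3000) {
    warning(sprintf("HU %g outside [-1024, 3000]; clamped", hu))
    hu <- min(max(hu, -1024), 3000)
  }
  anchors <- hu_anchor_table()
  if (hu <= -1000) return(default_materials()[material_row(default_materials(), "air"), ])
  if (hu == 0) return(default_materials()[material_row(default_materials(), "water"), ])
  interp <- function(col) approx(anchors$hu, anchors[[col]], xout = hu, rule = 2)$y
  material_spec(sprintf("hu_%d", round(hu)), interp("density"), interp("rsp"),
                interp("radiation_length"), interp("ionization"),
                nuclear_scale = interp("rsp"))
}

# the configured anchor table behind hu_to_material
hu_anchor_table <- function() {
  data.frame(hu = c(-1000, 0, 1500, 3000),
             density = c(0.0012, 1.000, 1.850, 2.700),
             rsp = c(0.0011, 1.00, 1.60, 2.30),
             radiation_length = c(36.62, 36.08, 16.60, 12.00),
             ionization = c(85.7, 75.0, 112.0, 135.0))
}
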