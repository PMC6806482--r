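#' Save / load dose cubes and phantoms
#'
#' Cubes and phantoms persist as RDS (exact round trip) with a plain-text
#' JSON sidecar describing shape, spacing, origin and (for phantoms) the
#' material table, so containers remain inspectable without R.
#'
#' @param x a [dose_cube()] or [voxel_phantom()].
#' @param path output path (`.rds`; the sidecar gets `.json` appended).
#' @return [read_container()] returns the stored object.
#' @export
write_container <- function(x, path) {
  stopifnot(inherits(x, "dose_cube") || inherits(x, "voxel_phantom"))
  saveRDS(x, path)
  hdr <- list(class = class(x)[1], dims = x$dims, spacing = x$spacing,
              origin = x$origin)
  if (inherits(x, "voxel_phantom")) hdr$materials <- x$materials$name
  if (inherits(x, "dose_cube")) hdr$engine <- x$engine
  writeLines(jsonlite::toJSON(hdr, digits = NA, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)

#' Export a dose cube as NIfTI
#'
#' Interoperability escape hatch for viewing cubes in standard medical
#' imaging tools (requires the RNifti package).
#'
#' @param cube a [dose_cube()].
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_dose_nifti <- function(cube, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(cube$dose, pixdim = cube$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Plot a transverse slice of a dose cube
#'
#' @param x a [dose_cube()].
#' @param z slice depth (mm, cube coordinates); default the maximum-dose slice.
#' @param ... passed to [graphics::image()].
#' @export
plot.dose_cube <- function(x, z = NULL, ...) {
  ax <- cube_axes(x)
  k <- if (is.null(z)) which.max(apply(x$dose, 3, max)) else
    which.min(abs(ax[[3]] - z))
  image(ax[[1]], ax[[2]], x$dose[, , k],
        xlab = "x [mm]", ylab = "y [mm]",
        main = sprintf("%s dose, z = %.1f mm", x$engine, ax[[3]][k]), ...)
  invisible(x)
}

#' Plot a measured plane
#' @param x a `measured_plane`.
#' @param ... passed to [graphics::image()].
#' @export
plot.measured_plane <- function(x, ...) {
  image(x$x, x$y, x$values, xlab = "x [mm]", ylab = "y [mm]",
        main = sprintf("measured plane, d_m = %.1f mm", x$d_m), ...)
  invisible(x)
}
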