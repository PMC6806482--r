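#' Construct a voxel phantom
#'
#' Coordinates are right-handed, in mm, with the beam travelling along +z.
#' `origin` is the position of the center of voxel `[1,1,1]`; voxel extents
#' are half-open intervals `[c - spacing/2, c + spacing/2)`.
#'
#' @param material_index integer 3D array (values index rows of `materials`).
#' @param spacing voxel spacing per axis (mm), length 1 or 3, positive.
#' @param origin center of the first voxel (mm), length 3.
#' @param materials material table ([default_materials()]).
#' @param hu optional Hounsfield array of the same shape.
#' @param landmarks optional named list of geometric landmarks (e.g. the z
#'   of the downstream solid-water surface that measurement depths are
#'   referenced to).
#' @param masks optional named list of voxel index vectors (e.g. the
#'   heterogeneity voxels eligible for material override).
#' @return object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(material_index, spacing, origin = NULL,
                          materials = default_materials(), hu = NULL,
                          landmarks = list(), masks = list()) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dim(material_index)) == 3, all(spacing > 0),
            is.numeric(spacing))
  if (is.null(origin)) origin <- spacing / 2
  idx <- as.integer(material_index)
  if (any(idx < 1 | idx > nrow(materials)))
    stop("material_index refers to undefined materials")
  structure(list(dims = dim(material_index),
                 spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 material_index = array(idx, dim(material_index)),
                 materials = materials, hu = hu,
                 landmarks = landmarks, masks = masks),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("voxel phantom: %d x %d x %d voxels, spacing %s mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 3), collapse = " x ")))
  tab <- table(factor(x$materials$name[x$material_index],
                      levels = x$materials$name))
  cat("materials:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# voxel-center coordinate vectors
phantom_axes <- function(ph) {
  lapply(1:3, function(a) ph$origin[a] + (seq_len(ph$dims[a]) - 1) * ph$spacing[a])
}

# outer (upstream) z edge of the grid
phantom_z_front <- function(ph) ph$origin[3] - ph$spacing[3] / 2

#' Build a layered slab phantom
#'
#' Stacks laterally uniform material layers along +z (e.g. water behind
#' solid-water buildup). Layers whose thickness is not a voxel multiple are
#' assigned by dominant occupancy, with a warning.
#'
#' @param layers list of `list(material, thickness_mm)` entries, ordered
#'   upstream to downstream.
#' @param lateral_size lateral extent (mm), length 1 or 2.
#' @param spacing voxel spacing (mm), length 1 or 3.
#' @param materials material table.
#' @return a [voxel_phantom()]; lateral center at (0, 0), upstream face at
#'   z = 0.
#' @export
build_slab_phantom <- function(layers, lateral_size = 100, spacing = 1,
                               materials = default_materials()) {
  if (length(lateral_size) == 1) lateral_size <- rep(lateral_size, 2)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  thick <- vapply(layers, function(l) as.numeric(l[[2]]), 0)
  names <- vapply(layers, function(l) as.character(l[[1]]), "")
  stopifnot(all(thick >= 0))
  rows <- vapply(names, material_row, 0L, materials = materials)
  total <- sum(thick)
  nz <- max(1L, as.integer(round(total / spacing[3])))
  nx <- max(1L, as.integer(round(lateral_size[1] / spacing[1])))
  ny <- max(1L, as.integer(round(lateral_size[2] / spacing[2])))
  off <- abs(thick / spacing[3] - round(thick / spacing[3]))
  if (any(off > 1e-6))
    warning("layer thickness not a voxel multiple; assigned by dominant occupancy")
  bounds <- cumsum(c(0, thick))
  slice <- integer(nz)
  for (k in seq_len(nz)) {
    z0 <- (k - 1) * spacing[3]; z1 <- k * spacing[3]
    ov <- pmax(0, pmin(bounds[-1], z1) - pmax(bounds[-length(bounds)], z0))
    slice[k] <- rows[which.max(ov)]
  }
  mat <- array(rep(slice, each = nx * ny), dim = c(nx, ny, nz))
  voxel_phantom(mat, spacing,
                origin = c(-lateral_size[1] / 2 + spacing[1] / 2,
                           -lateral_size[2] / 2 + spacing[2] / 2,
                           spacing[3] / 2),
                materials = materials,
                landmarks = list(surface_z = 0))
}

#' Configuration for the synthetic neck analog
#'
#' A soft-tissue cylinder (axis along x, beam along +z) containing a
#' cortical-bone annulus with an air cavity in its hollow, cut flat just
#' past the bone and backed by a solid-water measurement stack -- the
#' discrete bone/air lateral heterogeneity motif of an animal-neck phantom.
#' All radii are nested: air inside the bone annulus inside the tissue.
#'
#' @param tissue_radius soft-tissue cylinder radius (mm).
#' @param bone_r_inner,bone_r_outer bone annulus radii (mm).
#' @param air_radius air cavity radius (mm; 0 removes the cavity).
#' @param structure_offset (y, z) offset of the annulus/cavity center from
#'   the cylinder center (mm).
#' @param flat_cut distance from the cylinder center to the flat cut plane
#'   (mm); tissue beyond it is removed.
#' @param downstream_sw solid-water stack thickness behind the cut (mm).
#' @param lateral_size grid extent (x, y) in mm.
#' @param spacing voxel spacing (mm).
#' @return named list of class `neck_config`.
#' @export
neck_analog_config <- function(tissue_radius = 35, bone_r_inner = 4,
                               bone_r_outer = 7, air_radius = 2.5,
                               structure_offset = c(0, 0), flat_cut = 18,
                               downstream_sw = 55, lateral_size = c(70, 90),
                               spacing = 1) {
  structure(list(tissue_radius = tissue_radius, bone_r_inner = bone_r_inner,
                 bone_r_outer = bone_r_outer, air_radius = air_radius,
                 structure_offset = structure_offset, flat_cut = flat_cut,
                 downstream_sw = downstream_sw, lateral_size = lateral_size,
                 spacing = spacing), class = "neck_config")
}

#' Build the synthetic neck analog phantom
#'
#' @param config a [neck_analog_config()].
#' @param materials material table.
#' @return a [voxel_phantom()] with landmark `surface_z` (the downstream
#'   solid-water surface that measurement depths `d_m` are referenced to)
#'   and mask `heterogeneity` (bone + air-cavity voxels, the override
#'   volume for uniform-plan optimization).
#' @export
build_neck_analog <- function(config = neck_analog_config(),
                              materials = default_materials()) {
  c_ <- config
  if (!(c_$air_radius <= c_$bone_r_inner && c_$bone_r_inner < c_$bone_r_outer &&
        c_$bone_r_outer <= c_$tissue_radius))
    stop("radii must be nested: air <= bone inner < bone outer <= tissue")
  if (c_$flat_cut < c_$bone_r_outer + abs(c_$structure_offset[2]))
    stop("flat cut must lie past the bone annulus")
  sp <- if (length(c_$spacing) == 1) rep(c_$spacing, 3) else c_$spacing
  zc <- c_$tissue_radius               # cylinder center depth; surface tangent at z = 0
  flat_z <- zc + c_$flat_cut
  ztot <- flat_z + c_$downstream_sw
  nx <- as.integer(round(c_$lateral_size[1] / sp[1]))
  ny <- as.integer(round(c_$lateral_size[2] / sp[2]))
  nz <- as.integer(round(ztot / sp[3]))
  ys <- -c_$lateral_size[2] / 2 + (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]

  i_air <- material_row(materials, "air")
  i_tis <- material_row(materials, "soft_tissue")
  i_bone <- material_row(materials, "bone")
  i_sw <- material_row(materials, "solid_water")

  yz <- expand.grid(y = ys, z = zs)
  r_cyl <- sqrt(yz$y^2 + (yz$z - zc)^2)
  sy <- c_$structure_offset[1]; sz <- zc + c_$structure_offset[2]
  r_str <- sqrt((yz$y - sy)^2 + (yz$z - sz)^2)
  m <- rep(i_air, nrow(yz))
  inside <- r_cyl <= c_$tissue_radius & yz$z <= flat_z
  m[inside] <- i_tis
  m[inside & r_str <= c_$bone_r_outer & r_str > c_$bone_r_inner] <- i_bone
  if (c_$air_radius > 0) m[inside & r_str <= c_$air_radius] <- i_air
  m[yz$z > flat_z] <- i_sw
  plane <- matrix(m, nrow = ny, ncol = nz)   # [y, z]
  mat <- array(rep(plane, each = nx), dim = c(nx, ny, nz))

  het <- which(array(rep(matrix(
    inside & r_str <= c_$bone_r_outer, ny, nz), each = nx),
    dim = c(nx, ny, nz)))
  voxel_phantom(mat, sp,
                origin = c(-c_$lateral_size[1] / 2 + sp[1] / 2,
                           -c_$lateral_size[2] / 2 + sp[2] / 2, sp[3] / 2),
                materials = materials,
                landmarks = list(surface_z = flat_z, cylinder_center_z = zc,
                                 structure_center = c(y = sy, z = sz)),
                masks = list(heterogeneity = het))
}

#' Build the water-breast analog phantom
#'
#' A water hemisphere (breast analog, default radius 45 mm, flat side down)
#' resting on a solid-water measurement stack; the beam enters through the
#' dome. Oblique incidence is realized by [rotate_phantom()].
#'
#' @param radius hemisphere radius (mm).
#' @param slab_thickness solid-water stack thickness (mm).
#' @param lateral_size grid extent (x, y) mm.
#' @param spacing voxel spacing (mm).
#' @param materials material table.
#' @return a [voxel_phantom()] with landmark `surface_z` at the
#'   dome/solid-water interface.
#' @export
build_breast_analog <- function(radius = 45, slab_thickness = 50,
                                lateral_size = c(110, 110), spacing = 1,
                                materials = default_materials()) {
  sp <- if (length(spacing) == 1) rep(spacing, 3) else spacing
  nx <- as.integer(round(lateral_size[1] / sp[1]))
  ny <- as.integer(round(lateral_size[2] / sp[2]))
  nz <- as.integer(round((radius + slab_thickness) / sp[3]))
  xs <- -lateral_size[1] / 2 + (seq_len(nx) - 0.5) * sp[1]
  ys <- -lateral_size[2] / 2 + (seq_len(ny) - 0.5) * sp[2]
  zs <- (seq_len(nz) - 0.5) * sp[3]
  i_air <- material_row(materials, "air")
  i_w <- material_row(materials, "water")
  i_sw <- material_row(materials, "solid_water")
  mat <- array(i_air, dim = c(nx, ny, nz))
  r2 <- outer(xs^2, ys^2, "+")
  for (k in seq_len(nz)) {
    if (zs[k] <= radius) {
      mat[, , k][r2 <= radius^2 - (radius - zs[k])^2] <- i_w
    } else mat[, , k] <- i_sw
  }
  voxel_phantom(mat, sp,
                origin = c(xs[1], ys[1], zs[1]), materials = materials,
                landmarks = list(surface_z = radius))
}

#' Build a phantom from a Hounsfield-unit volume
#'
#' Optional import path for externally produced voxel volumes: HU values
#' are quantized into bins and each bin is mapped to a material through the
#' piecewise-linear calibration of [hu_to_material()].
#'
#' @param hu 3D array of Hounsfield values.
#' @param spacing voxel spacing (mm), length 1 or 3.
#' @param origin center of the first voxel (mm); default grid-corner based.
#' @param bin_width HU quantization step (default 50).
#' @return a [voxel_phantom()] whose material table holds one entry per
#'   occupied HU bin; the original HU volume is kept in the `hu` field.
#' @export
phantom_from_hu <- function(hu, spacing, origin = NULL, bin_width = 50) {
  stopifnot(length(dim(hu)) == 3)
  hu_c <- pmin(pmax(hu, -1024), 3000)
  bins <- round(hu_c / bin_width) * bin_width
  ub <- sort(unique(as.numeric(bins)))
  mats <- do.call(rbind, lapply(ub, function(b)
    suppressWarnings(hu_to_material(b))))
  mats$name <- sprintf("hu_%d", ub)
  class(mats) <- c("material_table", "data.frame")
  idx <- array(match(bins, ub), dim(hu))
  voxel_phantom(idx, spacing, origin, materials = mats, hu = hu)
}

#' Override heterogeneity materials to water
#'
#' Reproduces the planning trick of overriding the contoured heterogeneity
#' volumes to water before optimizing, then removing the override for the
#' final dose calculation.
#'
#' @param phantom a phantom with a `heterogeneity` mask.
#' @param to target material name (default water).
#' @return the phantom with masked voxels replaced.
#' @export
override_heterogeneity <- function(phantom, to = "water") {
  mask <- phantom$masks$heterogeneity
  if (is.null(mask) || length(mask) == 0) return(phantom)
  phantom$material_index[mask] <- material_row(phantom$materials, to)
  phantom
}

#' Water-equivalent depth along a ray
#'
#' Exact voxel raytracing: sums segment-length times relative stopping
#' power over the voxels traversed, up to `geometric_depth` along the ray.
#'
#' @param phantom a [voxel_phantom()].
#' @param entry ray start point (mm, length 3).
#' @param direction direction vector (normalized internally).
#' @param geometric_depth geometric path length to integrate (mm).
#' @return water-equivalent depth (mm), with attribute `hit` (FALSE when
#'   the ray misses the grid, in which case 0 is returned).
#' @export
wed_along_ray <- function(phantom, entry, direction, geometric_depth) {
  stopifnot(geometric_depth >= 0)
  r <- wed_ray_cpp(phantom$material_index - 1L, as.integer(phantom$dims),
                   phantom$spacing, phantom$origin,
                   phantom$materials$rsp, as.numeric(entry),
                   as.numeric(direction), geometric_depth)
  structure(r$wed, hit = r$hit)
}

# cumulative WED profile down the +z column through (x, y), evaluated at
# arbitrary z positions (mm), measured from the grid's upstream face
wed_column <- function(phantom, x, y, z) {
  wed_column_cpp(phantom$material_index - 1L, as.integer(phantom$dims),
                 phantom$spacing, phantom$origin, phantom$materials$rsp,
                 x, y, as.numeric(z))
}

#' Resample a phantom to a new grid spacing
#'
#' Nearest-neighbor material sampling at the new voxel centers over the
#' same physical extent (used to put dose grids at 1 or 2 mm).
#'
#' @param phantom a [voxel_phantom()].
#' @param spacing new spacing (mm, length 1 or 3).
#' @return a [voxel_phantom()].
#' @export
resample_phantom <- function(phantom, spacing) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (isTRUE(all.equal(spacing, phantom$spacing))) return(phantom)
  ext <- phantom$dims * phantom$spacing
  lo <- phantom$origin - phantom$spacing / 2
  nd <- pmax(1L, as.integer(round(ext / spacing)))
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(nd[a]) - 0.5) * spacing[a])
  ia <- lapply(1:3, function(a) {
    i <- as.integer(floor((ax[[a]] - lo[a]) / phantom$spacing[a])) + 1L
    pmin(pmax(i, 1L), phantom$dims[a])
  })
  mat <- phantom$material_index[ia[[1]], ia[[2]], ia[[3]], drop = FALSE]
  voxel_phantom(array(mat, nd), spacing,
                origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]),
                materials = phantom$materials,
                landmarks = phantom$landmarks)
}

#' Rotate a phantom into beam-eye-view
#'
#' Both dose engines transport along +z; oblique incidence is realized by
#' resampling the phantom onto a grid rotated about the x axis through a
#' pivot point (nearest-neighbor lookup; voxels sampled outside the
#' original grid become air).
#'
#' @param phantom a [voxel_phantom()].
#' @param angle_deg rotation angle about +x (degrees).
#' @param pivot rotation center (mm); defaults to the grid center.
#' @return a [voxel_phantom()] on a grid of the same shape.
#' @export
rotate_phantom <- function(phantom, angle_deg, pivot = NULL) {
  if (abs(angle_deg) < 1e-12) return(phantom)
  if (is.null(pivot)) pivot <- phantom$origin + (phantom$dims - 1) * phantom$spacing / 2
  th <- angle_deg * pi / 180
  ax <- phantom_axes(phantom)
  i_air <- material_row(phantom$materials, "air")
  nd <- phantom$dims
  yz <- expand.grid(y = ax[[2]] - pivot[2], z = ax[[3]] - pivot[3])
  ys <- pivot[2] + cos(th) * yz$y - sin(th) * yz$z
  zs <- pivot[3] + sin(th) * yz$y + cos(th) * yz$z
  lo <- phantom$origin - phantom$spacing / 2
  j <- as.integer(floor((ys - lo[2]) / phantom$spacing[2])) + 1L
  k <- as.integer(floor((zs - lo[3]) / phantom$spacing[3])) + 1L
  ok <- j >= 1 & j <= nd[2] & k >= 1 & k <= nd[3]
  src <- ifelse(ok, j + (k - 1L) * nd[2], NA_integer_)
  out <- array(i_air, nd)
  for (i in seq_len(nd[1])) {
    pm <- phantom$material_index[i, , ]
    sl <- pm[src]
    sl[is.na(sl)] <- i_air
    out[i, , ] <- sl
  }
  voxel_phantom(out, phantom$spacing, phantom$origin, phantom$materials,
                landmarks = phantom$landmarks)
}
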