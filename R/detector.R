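#' Virtual planar ionization-chamber array measurement
#'
#' Emulates a MatriXX-PT-style detector placed behind a stack of
#' solid-water slabs: the effective measurement plane sits at
#' water-equivalent depth `d_m = stack_mm * 1.03 + buildup_wet` below the
#' phantom's downstream solid-water surface (6 mm of water-equivalent
#' buildup is intrinsic to the detector), the dose cube is sampled
#' trilinearly on the 7-mm detector lattice at that plane, and each channel
#' is scaled by a cross-calibration factor and perturbed by multiplicative
#' Gaussian noise.
#'
#' @param cube a [dose_cube()].
#' @param stack_mm physical solid-water stack thickness between surface and
#'   detector (mm).
#' @param surface_z z of the solid-water surface in cube coordinates (mm);
#'   defaults to the phantom landmark stored in `cube$meta$surface_z` if
#'   present.
#' @param pitch detector pitch (mm), default 7.
#' @param n_det detectors per axis (length 1 or 2), default 24.
#' @param center lateral center of the array (mm).
#' @param buildup_wet intrinsic water-equivalent buildup (mm), default 6.
#' @param sw_rsp relative stopping power of the solid-water stack (1.03).
#' @param calibration_factor multiplicative cross-calibration.
#' @param noise_sigma per-channel relative noise standard deviation
#'   (default 0.01).
#' @param seed RNG seed for the noise (isolated from the caller's RNG).
#' @param average_kernel_mm optional diameter of a circular averaging
#'   kernel emulating the chamber area (0 = point sampling, the default).
#' @return object of class `measured_plane`: detector values (Gy) with the
#'   lattice coordinates, `d_m`, and the plane's absolute z in cube
#'   coordinates (`z_plane`).
#' @export
simulate_measurement <- function(cube, stack_mm, surface_z = NULL, pitch = 7,
                                 n_det = 24, center = c(0, 0),
                                 buildup_wet = 6, sw_rsp = 1.03,
                                 calibration_factor = 1, noise_sigma = 0.01,
                                 seed = 1, average_kernel_mm = 0) {
  if (is.null(surface_z)) surface_z <- cube$meta$surface_z
  if (is.null(surface_z)) stop("surface_z required (no landmark in cube meta)")
  if (length(n_det) == 1) n_det <- rep(n_det, 2)
  d_m <- stack_mm * sw_rsp + buildup_wet
  z_plane <- surface_z + d_m / sw_rsp   # physical depth in the solid-water stack
  ax <- cube_axes(cube)
  if (z_plane < min(ax[[3]]) || z_plane > max(ax[[3]]))
    stop(sprintf("measurement plane z=%.1f outside cube [%.1f, %.1f]",
                 z_plane, min(ax[[3]]), max(ax[[3]])))
  xs <- center[1] + pitch * (seq_len(n_det[1]) - (n_det[1] + 1) / 2)
  ys <- center[2] + pitch * (seq_len(n_det[2]) - (n_det[2] + 1) / 2)
  sample_at <- function(dzoff = 0, dxoff = 0, dyoff = 0)
    extract_plane(cube, z_plane + dzoff, xs + dxoff, ys + dyoff)
  vals <- sample_at()
  if (average_kernel_mm > 0) {
    r <- average_kernel_mm / 2
    off <- expand.grid(dx = c(-r, 0, r), dy = c(-r, 0, r))
    off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, ]
    acc <- 0
    for (i in seq_len(nrow(off)))
      acc <- acc + sample_at(0, off$dx[i], off$dy[i])
    vals <- acc / nrow(off)
  }
  noise <- if (noise_sigma > 0)
    with_seed(seed, matrix(rnorm(length(vals), 0, noise_sigma), nrow(vals)))
  else 0
  vals <- pmax(vals * calibration_factor * (1 + noise), 0)
  structure(list(values = vals, x = xs, y = ys, pitch = pitch, d_m = d_m,
                 z_plane = z_plane, buildup_wet = buildup_wet,
                 calibration_factor = calibration_factor,
                 noise_sigma = noise_sigma),
            class = "measured_plane")
}

#' @export
print.measured_plane <- function(x, ...) {
  cat(sprintf("measured plane: %d x %d detectors @ %.1f mm pitch, d_m = %.2f mm, max %.4g Gy\n",
              length(x$x), length(x$y), x$pitch, x$d_m, max(x$values)))
  invisible(x)
}

#' Write / read an OPG-style ASCII plane
#'
#' Minimal self-defined dialect of the Omni Pro Generic ASCII format: a
#' `<opg>` header block with dose unit, pitch, origin and depth metadata,
#' followed by an `<asciibody>` row-major value matrix. Read and write are
#' inverse to within 1e-6 Gy; CRLF files parse identically to LF.
#'
#' @param plane a `measured_plane`.
#' @param path file path.
#' @return [read_opg()] returns a `measured_plane`.
#' @export
write_opg <- function(plane, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("<opg>",
               "Data Type: Absolute Dose",
               "Data Unit: Gy",
               sprintf("Pitch [mm]: %.6g", plane$pitch),
               sprintf("Origin X [mm]: %.6g", plane$x[1]),
               sprintf("Origin Y [mm]: %.6g", plane$y[1]),
               sprintf("Depth dm [mm]: %.6g", plane$d_m),
               sprintf("Buildup WET [mm]: %.6g", plane$buildup_wet),
               sprintf("Calibration Factor: %.8g", plane$calibration_factor),
               sprintf("Rows: %d", length(plane$x)),
               sprintf("Cols: %d", length(plane$y)),
               "<asciibody>"), con)
  for (i in seq_along(plane$x))
    writeLines(paste(sprintf("%.7e", plane$values[i, ]), collapse = "\t"), con)
  writeLines("</asciibody>", con)
  invisible(path)
}

#' @rdname write_opg
#' @export
read_opg <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  if (length(lines) == 0 || lines[1] != "<opg>")
    stop("not an OPG plane: missing <opg> header (line 1)")
  body_at <- match("<asciibody>", lines)
  if (is.na(body_at)) stop("malformed OPG file: no <asciibody> marker")
  hdr <- lines[2:(body_at - 1)]
  get <- function(key, required = TRUE) {
    hit <- grep(paste0("^", key, ":"), hdr, value = TRUE)
    if (length(hit) == 0) {
      if (required) stop(sprintf("malformed OPG header: missing '%s'", key))
      return(NA)
    }
    sub(".*:\\s*", "", hit[1])
  }
  if (!identical(get("Data Unit"), "Gy"))
    stop("unsupported OPG dose unit (expected Gy)")
  pitch <- as.numeric(get("Pitch \\[mm\\]"))
  ox <- as.numeric(get("Origin X \\[mm\\]"))
  oy <- as.numeric(get("Origin Y \\[mm\\]"))
  dm <- as.numeric(get("Depth dm \\[mm\\]"))
  bw <- as.numeric(get("Buildup WET \\[mm\\]"))
  cf <- as.numeric(get("Calibration Factor"))
  nr <- as.integer(get("Rows"))
  nc <- as.integer(get("Cols"))
  end_at <- match("</asciibody>", lines)
  if (is.na(end_at)) end_at <- length(lines) + 1
  rows <- lines[(body_at + 1):(end_at - 1)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != nr)
    stop(sprintf("OPG body has %d rows, header declares %d (line %d)",
                 length(rows), nr, body_at + 1 + min(length(rows), nr)))
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    v <- as.numeric(strsplit(rows[i], "[\t ]+")[[1]])
    if (length(v) != nc)
      stop(sprintf("OPG row %d has %d values, header declares %d (line %d)",
                   i, length(v), nc, body_at + i))
    vals[i, ] <- v
  }
  structure(list(values = vals, x = ox + pitch * (seq_len(nr) - 1),
                 y = oy + pitch * (seq_len(nc) - 1), pitch = pitch,
                 d_m = dm, z_plane = NA_real_, buildup_wet = bw,
                 calibration_factor = cf, noise_sigma = NA_real_),
            class = "measured_plane")
}

#' Interpolate a measured plane to a finer grid
#'
#' Bilinear interpolation of the detector lattice onto a regular grid
#' (default 2 mm), the resampling applied to measurements before 2D gamma
#' analysis.
#'
#' @param plane a `measured_plane`.
#' @param spacing target grid spacing (mm).
#' @return list with `values`, `x`, `y`.
#' @export
interp_plane_to_grid <- function(plane, spacing = 2) {
  xs <- seq(min(plane$x), max(plane$x), by = spacing)
  ys <- seq(min(plane$y), max(plane$y), by = spacing)
  list(values = bilinear_resample(plane$values, plane$x, plane$y, xs, ys),
       x = xs, y = ys)
}

# separable bilinear resampling of a matrix from (sx, sy) to (dx, dy)
bilinear_resample <- function(values, sx, sy, dx, dy) {
  wmat <- function(src, dst) {
    if (length(src) == 1) return(matrix(1, length(dst), 1))
    i <- findInterval(dst, src, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(src) - 1)
    w <- (dst - src[i]) / (src[i + 1] - src[i])
    w <- pmin(pmax(w, 0), 1)
    M <- matrix(0, length(dst), length(src))
    M[cbind(seq_along(dst), i)] <- 1 - w
    M[cbind(seq_along(dst), i + 1)] <- M[cbind(seq_along(dst), i + 1)] + w
    M
  }
  Wx <- wmat(sx, dx); Wy <- wmat(sy, dy)
  Wx %*% values %*% t(Wy)
}
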