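#' Parallel-beam projection geometry
#'
#' Describes how a slice is observed: an ordered list of view angles over a
#' full rotation, the number of detector bins and their physical pitch, and
#' the rotation-centre position on the detector. Angle 0 corresponds to rays
#' running along image rows; angles increase counter-clockwise. All detector
#' and angle indices in this package are 0-based, matching the acquisition
#' manifest convention.
#'
#' @param angles_deg strictly increasing numeric vector, each in `[0, 360)`.
#' @param n_detector number of detector bins (must be at least the side
#'   length of any image projected with this geometry).
#' @param detector_pitch physical width of one detector bin (micrometres).
#' @param rotation_center centre of rotation in detector-bin units
#'   (0-based); defaults to the detector midpoint `(n_detector - 1) / 2`.
#' @return an object of class `projection_geometry`.
#' @examples
#' geom <- projection_geometry(evenly_spaced_angles(16), n_detector = 32)
#' geom$angles_deg[1:4]
#' @export
projection_geometry <- function(angles_deg, n_detector,
                                detector_pitch = 1,
                                rotation_center = (n_detector - 1) / 2) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 1L || anyNA(angles_deg))
    abort("projection_geometry: empty or invalid angle list")
  if (any(angles_deg < 0 | angles_deg >= 360))
    abort("projection_geometry: angles must lie in [0, 360)")
  if (is.unsorted(angles_deg, strictly = TRUE))
    abort("projection_geometry: angles must be strictly increasing")
  stopifnot(is_scalar_num(n_detector), n_detector >= 1,
            is_scalar_num(detector_pitch), detector_pitch > 0,
            is_scalar_num(rotation_center))
  structure(list(angles_deg = angles_deg,
                 n_detector = as.integer(n_detector),
                 detector_pitch = detector_pitch,
                 rotation_center = rotation_center),
            class = "projection_geometry")
}

#' @rdname projection_geometry
#' @param n number of evenly spaced angles over the full 360 degree rotation.
#' @export
evenly_spaced_angles <- function(n) {
  stopifnot(is_scalar_num(n), n >= 1)
  seq(0, 360, length.out = n + 1)[seq_len(n)]
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> %d angles in [%.4g, %.4g) deg, %d bins @ %.3g um, center %.3f\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              x$n_detector, x$detector_pitch, x$rotation_center))
  invisible(x)
}

#' Sinogram container
#'
#' One slice's measurement: a matrix of line integrals, one row per view
#' angle, one column per detector bin, tagged with its geometry and channel.
#'
#' @param values numeric matrix, `length(geometry$angles_deg)` rows and
#'   `geometry$n_detector` columns.
#' @param geometry a [projection_geometry()].
#' @param channel `"fluorescence"` or `"transmission-converted"`.
#' @param slice_index 0-based index of the originating slice.
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geometry,
                     channel = c("fluorescence", "transmission-converted"),
                     slice_index = 0L) {
  channel <- match.arg(channel)
  values <- as.matrix(values)
  if (!inherits(geometry, "projection_geometry"))
    abort("sinogram: `geometry` must be a projection_geometry")
  if (nrow(values) != length(geometry$angles_deg))
    abort("sinogram: row count (%d) must equal the angle count (%d)",
          nrow(values), length(geometry$angles_deg))
  if (ncol(values) != geometry$n_detector)
    abort("sinogram: column count (%d) must equal n_detector (%d)",
          ncol(values), geometry$n_detector)
  if (!all(is.finite(values))) abort("sinogram: values must be finite")
  structure(list(values = values, geometry = geometry, channel = channel,
                 slice_index = as.integer(slice_index)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, channel %s, slice %d\n",
              nrow(x$values), ncol(x$values), x$channel, x$slice_index))
  invisible(x)
}

#' Projection stack container
#'
#' Per-slice sinograms for a whole volume, sharing one geometry: a 3-D array
#' `[angle, detector bin, slice]` plus acquisition metadata.
#'
#' @param values numeric array `[n_angles, n_detector, n_slices]`.
#' @param geometry a [projection_geometry()].
#' @param channel measurement channel tag.
#' @param noise_sd standard deviation of the additive measurement noise.
#' @param seed RNG seed the stack was simulated with (`NA` for real data).
#' @param source identifier of the originating specimen/phantom.
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(values, geometry,
                             channel = c("fluorescence", "transmission-converted"),
                             noise_sd = 0, seed = NA_integer_, source = "") {
  channel <- match.arg(channel)
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("projection_stack: `values` must be a 3-D array [angle, bin, slice]")
  if (dim(values)[1] != length(geometry$angles_deg) ||
      dim(values)[2] != geometry$n_detector)
    abort("projection_stack: array dims inconsistent with geometry")
  if (!all(is.finite(values))) abort("projection_stack: values must be finite")
  structure(list(values = values, geometry = geometry, channel = channel,
                 noise_sd = noise_sd, seed = seed, source = source),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection_stack> %d angles x %d bins x %d slices, channel %s, noise_sd %.4g\n",
              d[1], d[2], d[3], x$channel, x$noise_sd))
  invisible(x)
}

#' Number of slices in a projection stack
#' @param stack a [projection_stack()].
#' @return integer slice count.
#' @export
n_slices <- function(stack) dim(stack$values)[3]

#' Extract one slice's sinogram from a stack
#' @param stack a [projection_stack()].
#' @param k 1-based slice index.
#' @return a [sinogram()].
#' @export
get_sinogram <- function(stack, k) {
  stopifnot(k >= 1, k <= n_slices(stack))
  sinogram(stack$values[, , k, drop = TRUE], stack$geometry,
           channel = stack$channel, slice_index = k - 1L)
}

# ---- Radon system matrix -------------------------------------------------

# Ray-driven parallel-beam projector for a square side x side image, built
# once per (side, geometry) and cached as a sparse matrix. Each (angle, bin)
# row samples the image bilinearly at unit steps along its ray and sums the
# samples, scaled by detector_pitch (the step length in physical units), so
# a row approximates the physical line integral. back_project() uses the
# exact matrix transpose, which makes the adjoint identity hold to machine
# precision.
radon_system_matrix <- function(side, geom) {
  key <- paste(side, geom$n_detector, signif(geom$detector_pitch, 12),
               signif(geom$rotation_center, 12),
               paste(signif(geom$angles_deg, 12), collapse = ","), sep = "|")
  hit <- .optomo_cache[[key]]
  if (!is.null(hit)) return(hit)

  th <- geom$angles_deg * pi / 180
  nd <- geom$n_detector
  cpix <- (side - 1) / 2
  half <- side * sqrt(2) / 2 + 1
  u <- seq(-ceiling(half), ceiling(half), by = 1)   # sample offsets along the ray
  dbin <- seq_len(nd) - 1 - geom$rotation_center    # detector offsets from center

  ti <- tj <- tx <- vector("list", length(th))
  for (k in seq_along(th)) {
    ct <- cos(th[k]); st <- sin(th[k])
    # sample positions: p = dbin * (ct, st) + u * (-st, ct), centered coords
    px <- rep(dbin * ct, each = length(u)) + rep(-st * u, times = nd) + cpix
    py <- rep(dbin * st, each = length(u)) + rep(ct * u, times = nd) + cpix
    bin <- rep(seq_len(nd), each = length(u))
    i0 <- floor(px); j0 <- floor(py)
    fx <- px - i0; fy <- py - j0
    keep <- i0 >= 0 & i0 <= side - 1 & j0 >= 0 & j0 <= side - 1
    # the four bilinear corners (clipped individually at the image border)
    corner <- function(di, dj, w) {
      ii <- i0 + di; jj <- j0 + dj
      ok <- keep & ii >= 0 & ii <= side - 1 & jj >= 0 & jj <= side - 1 & w > 0
      list(i = (k - 1L) * nd + bin[ok],
           j = ii[ok] + jj[ok] * side + 1L,
           x = w[ok])
    }
    cs <- list(corner(0L, 0L, (1 - fx) * (1 - fy)),
               corner(1L, 0L, fx * (1 - fy)),
               corner(0L, 1L, (1 - fx) * fy),
               corner(1L, 1L, fx * fy))
    ti[[k]] <- unlist(lapply(cs, `[[`, "i"))
    tj[[k]] <- unlist(lapply(cs, `[[`, "j"))
    tx[[k]] <- unlist(lapply(cs, `[[`, "x"))
  }
  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(length(th) * nd, side * side))
  A <- A * geom$detector_pitch
  .optomo_cache[[key]] <- A
  A
}

# ---- Operations ----------------------------------------------------------

#' Forward Radon projection of a slice
#'
#' Computes parallel-beam line integrals of a square image at every angle of
#' the geometry — the forward model of transmission/fluorescence projection
#' imaging. Linear in the image; its exact adjoint is [back_project()].
#'
#' @param image square numeric matrix or [slice_image()]; side must not
#'   exceed `geom$n_detector`.
#' @param geom a [projection_geometry()].
#' @param channel channel tag for the resulting sinogram.
#' @param slice_index 0-based slice index recorded in the sinogram.
#' @return a [sinogram()] with one row per angle.
#' @examples
#' img <- matrix(0, 32, 32); img[12:20, 12:20] <- 1
#' geom <- projection_geometry(evenly_spaced_angles(8), n_detector = 32)
#' sino <- radon_forward(img, geom)
#' rowSums(sino$values)[1:3]  # each row integrates the same mass
#' @export
radon_forward <- function(image, geom, channel = "fluorescence",
                          slice_index = 0L) {
  image <- as.matrix(image)
  side <- nrow(image)
  if (side != ncol(image))
    abort("radon_forward: image must be square (pad upstream)")
  if (side > geom$n_detector)
    abort("radon_forward: image side (%d) exceeds n_detector (%d)",
          side, geom$n_detector)
  A <- radon_system_matrix(side, geom)
  y <- as.numeric(A %*% as.numeric(image))
  vals <- t(matrix(y, nrow = geom$n_detector))
  sinogram(vals, geom, channel = channel, slice_index = slice_index)
}

#' Unfiltered back projection (adjoint of the forward projector)
#'
#' Smears each sinogram row back across the image along its ray direction.
#' This is the exact matrix transpose of [radon_forward()] under the same
#' discretisation, so the adjoint identity `<Rx, y> == <x, R^T y>` holds to
#' machine precision.
#'
#' @param sino a [sinogram()].
#' @param out_side side length of the output image; at most `n_detector`.
#' @return a [slice_image()].
#' @export
back_project <- function(sino, out_side) {
  stopifnot(inherits(sino, "sinogram"))
  if (!is_scalar_num(out_side) || out_side < 1 ||
      out_side > sino$geometry$n_detector)
    abort("back_project: out_side must be in [1, n_detector]")
  out_side <- as.integer(out_side)
  A <- radon_system_matrix(out_side, sino$geometry)
  x <- as.numeric(Matrix::crossprod(A, as.numeric(t(sino$values))))
  slice_image(matrix(x, out_side, out_side))
}

#' Evenly spaced angular subset
#'
#' Indices of `n_keep` evenly spaced projections out of `n_total`, the
#' angular down-sampling scheme used to emulate shorter acquisitions:
#' `i_j = round(j * n_total / n_keep)` for `j = 0 ... n_keep - 1`
#' (half-up rounding). Exact integer steps whenever `n_keep` divides
#' `n_total` (e.g. 800 to 50 keeps every 16th view).
#'
#' @param n_total number of acquired projections.
#' @param n_keep number of projections to retain (`1 <= n_keep <= n_total`).
#' @return integer vector of `n_keep` distinct 0-based indices in
#'   `[0, n_total)`. Add 1 before subsetting R vectors.
#' @examples
#' downsample_angles(800, 32)[1:4]  # 0 25 50 75
#' @export
downsample_angles <- function(n_total, n_keep) {
  stopifnot(is_scalar_num(n_total), n_total >= 1,
            is_scalar_num(n_keep))
  if (n_keep < 1 || n_keep > n_total)
    abort("downsample_angles: need 1 <= n_keep (%s) <= n_total (%s)",
          format(n_keep), format(n_total))
  j <- seq_len(n_keep) - 1
  as.integer(round_half_up(j * n_total / n_keep))
}

#' Random angular subset
#'
#' `n_keep` distinct projection indices drawn uniformly without replacement,
#' used to estimate the sampling variability of down-sampled reconstructions.
#' Deterministic for a fixed seed.
#'
#' @inheritParams downsample_angles
#' @param seed integer RNG seed.
#' @return sorted integer vector of `n_keep` distinct 0-based indices.
#' @export
random_angle_subset <- function(n_total, n_keep, seed) {
  stopifnot(is_scalar_num(n_total), n_total >= 1, is_scalar_num(n_keep),
            is_scalar_num(seed))
  if (n_keep < 1 || n_keep > n_total)
    abort("random_angle_subset: need 1 <= n_keep <= n_total")
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(as.integer(n_total), as.integer(n_keep)))
  sort(as.integer(idx) - 1L)
}

#' Restrict a geometry or stack to an angular subset
#'
#' @param x a [projection_geometry()] or [projection_stack()].
#' @param indices 0-based angle indices (as returned by
#'   [downsample_angles()] or [random_angle_subset()]).
#' @return object of the same class restricted to those angles.
#' @export
subset_angles <- function(x, indices) {
  indices <- as.integer(indices)
  if (inherits(x, "projection_geometry")) {
    if (any(indices < 0 | indices >= length(x$angles_deg)))
      abort("subset_angles: index out of range")
    projection_geometry(x$angles_deg[indices + 1L], x$n_detector,
                        x$detector_pitch, x$rotation_center)
  } else if (inherits(x, "projection_stack")) {
    geom <- subset_angles(x$geometry, indices)
    projection_stack(x$values[indices + 1L, , , drop = FALSE], geom,
                     channel = x$channel, noise_sd = x$noise_sd,
                     seed = x$seed, source = x$source)
  } else {
    abort("subset_angles: unsupported input class")
  }
}

#' Convert transmission intensities to attenuation line integrals
#'
#' Beer-Lambert conversion `-log(I / I0)` per detector bin, so transmission
#' measurements fit the same linear projection model as fluorescence data.
#' Intensities are floored at `1e-6` of the bright reference before the log.
#'
#' @param intensity numeric matrix of detected intensities, one row per
#'   angle, or a [sinogram()]-shaped matrix.
#' @param bright_reference strictly positive reference (no-sample) intensity:
#'   a scalar or a per-bin vector of length `ncol(intensity)`.
#' @param geometry a [projection_geometry()] for the output sinogram.
#' @param slice_index 0-based slice index tag.
#' @return a [sinogram()] with channel `"transmission-converted"`.
#' @export
transmission_to_lineintegrals <- function(intensity, bright_reference,
                                          geometry, slice_index = 0L) {
  intensity <- as.matrix(intensity)
  if (any(!is.finite(intensity)) || min(intensity) < 0)
    abort("transmission_to_lineintegrals: intensities must be finite and >= 0")
  if (any(!is.finite(bright_reference)) || min(bright_reference) <= 0)
    abort("transmission_to_lineintegrals: bright_reference must be > 0")
  ref <- if (length(bright_reference) == 1L) {
    matrix(bright_reference, nrow(intensity), ncol(intensity))
  } else if (length(bright_reference) == ncol(intensity)) {
    matrix(bright_reference, nrow(intensity), ncol(intensity), byrow = TRUE)
  } else {
    abort("transmission_to_lineintegrals: bright_reference must be scalar or per-bin")
  }
  ratio <- pmax(intensity / ref, 1e-6)
  sinogram(-log(ratio), geometry, channel = "transmission-converted",
           slice_index = slice_index)
}
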