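#' Digital specimen specification
#'
#' Declares a seeded digital stand-in for a small transparent specimen with a
#' fluorescently labelled vascular network: a fluorescence channel made of
#' bright smooth tubes on a dark background, and a transmission (anatomy)
#' channel dominated by a few large high-contrast ellipsoids (the "eyes")
#' over a faint smooth body envelope. The same spec (including its seed)
#' always reproduces the identical phantom.
#'
#' @param shape integer vector `(ny, nx, nz)` of voxel grid dimensions;
#'   axis 3 is the rotation axis.
#' @param voxel_size physical voxel edge (micrometres).
#' @param vessel_count number of tubes in the fluorescence channel (>= 0).
#' @param radius_range length-2 numeric, min/max tube radius in voxels; the
#'   minimum resolvable radius is 1.5 voxels and radii may not exceed a
#'   quarter of the smallest grid side.
#' @param vessel_intensity fluorescence value inside a tube (> 0).
#' @param intensity_range length-2 fractions in (0, 1]; each tube's
#'   intensity is `vessel_intensity` times a factor drawn uniformly from
#'   this range. The default `c(1, 1)` gives every tube exactly
#'   `vessel_intensity`; a wider range emulates varying fluorophore
#'   concentration across the network.
#' @param anatomy_blobs list of ellipsoids, each a list with `center`
#'   (voxel coords, 1-based), `semi_axes` (voxels) and `intensity`.
#' @param background_intensity value outside structures (>= 0); also the
#'   level of the anatomy body envelope.
#' @param seed integer RNG seed.
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(shape = c(32, 32, 32), seed = 1)
#' vol <- make_vessel_phantom(spec)
#' range(vol)
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         voxel_size = 6.5,
                         vessel_count = 6,
                         radius_range = c(1.5, 4),
                         vessel_intensity = 100,
                         intensity_range = c(1, 1),
                         anatomy_blobs = default_anatomy_blobs(shape),
                         background_intensity = 0.1,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L),
            is_scalar_num(voxel_size), voxel_size > 0,
            is_scalar_num(vessel_count), vessel_count >= 0,
            length(radius_range) == 2L, all(is.finite(radius_range)),
            is_scalar_num(vessel_intensity), vessel_intensity > 0,
            length(intensity_range) == 2L, all(is.finite(intensity_range)),
            is.list(anatomy_blobs),
            is_scalar_num(background_intensity), background_intensity >= 0,
            is_scalar_num(seed))
  intensity_range <- sort(as.numeric(intensity_range))
  if (intensity_range[1] <= 0 || intensity_range[2] > 1)
    abort("phantom_spec: intensity_range fractions must lie in (0, 1]")
  radius_range <- sort(as.numeric(radius_range))
  if (radius_range[1] < 1.5)
    abort("phantom_spec: tube radius %.3g is below the 1.5-voxel resolution floor",
          radius_range[1])
  if (radius_range[2] > min(shape) / 4)
    abort("phantom_spec: max radius %.3g exceeds min(shape)/4 = %.3g",
          radius_range[2], min(shape) / 4)
  for (b in anatomy_blobs) {
    if (!all(c("center", "semi_axes", "intensity") %in% names(b)))
      abort("phantom_spec: each anatomy blob needs center, semi_axes, intensity")
    if (b$intensity < 0) abort("phantom_spec: blob intensity must be >= 0")
  }
  structure(list(shape = shape, voxel_size = voxel_size,
                 vessel_count = as.integer(vessel_count),
                 radius_range = radius_range,
                 vessel_intensity = vessel_intensity,
                 intensity_range = intensity_range,
                 anatomy_blobs = anatomy_blobs,
                 background_intensity = background_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_anatomy_blobs <- function(shape) {
  # two high-contrast "eyes" plus one mid-contrast organ; intensities are
  # attenuation-scale, >= 5x the 0.1 body envelope
  c1 <- c(0.35, 0.35, 0.35) * shape
  c2 <- c(0.35, 0.65, 0.35) * shape
  c3 <- c(0.60, 0.50, 0.55) * shape
  r_eye <- max(2, round(min(shape) * 0.10))
  list(
    list(center = c1, semi_axes = rep(r_eye, 3), intensity = 1.0),
    list(center = c2, semi_axes = rep(r_eye, 3), intensity = 1.0),
    list(center = c3, semi_axes = c(r_eye * 1.5, r_eye, r_eye * 1.5),
         intensity = 0.5)
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%dx%d, %d vessels r=[%.2g, %.2g], %d blobs, seed %d\n",
              x$shape[1], x$shape[2], x$shape[3], x$vessel_count,
              x$radius_range[1], x$radius_range[2],
              length(x$anatomy_blobs), x$seed))
  invisible(x)
}

# squared distance from every voxel in a bounding box to a 3-D segment
# returns list(index vector into the full array, distance vector)
segment_distance <- function(shape, p0, p1, reach) {
  lo <- pmax(1L, floor(pmin(p0, p1) - reach))
  hi <- pmin(shape, ceiling(pmax(p0, p1) + reach))
  if (any(lo > hi)) return(NULL)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  n <- length(gx) * length(gy) * length(gz)
  x <- rep(gx, times = length(gy) * length(gz))
  y <- rep(rep(gy, each = length(gx)), times = length(gz))
  z <- rep(gz, each = length(gx) * length(gy))
  d <- p1 - p0
  len2 <- sum(d * d)
  if (len2 < 1e-12) {
    dist <- sqrt((x - p0[1])^2 + (y - p0[2])^2 + (z - p0[3])^2)
  } else {
    tt <- ((x - p0[1]) * d[1] + (y - p0[2]) * d[2] + (z - p0[3]) * d[3]) / len2
    tt <- pmin(1, pmax(0, tt))
    dist <- sqrt((x - (p0[1] + tt * d[1]))^2 +
                 (y - (p0[2] + tt * d[2]))^2 +
                 (z - (p0[3] + tt * d[3]))^2)
  }
  idx <- x + (y - 1) * shape[1] + (z - 1) * shape[1] * shape[2]
  list(idx = idx, dist = dist)
}

# random piecewise-linear centerline across the grid
random_centerline <- function(shape, n_segments = 4L) {
  start <- runif(3, 0.15, 0.85) * shape
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  step <- max(shape) / n_segments
  pts <- matrix(0, n_segments + 1L, 3)
  pts[1, ] <- start - dir * step * n_segments / 2
  for (s in seq_len(n_segments)) {
    dir <- dir + rnorm(3, sd = 0.25)
    dir <- dir / sqrt(sum(dir^2))
    pts[s + 1L, ] <- pts[s, ] + dir * step
  }
  pts
}

#' Generate the fluorescence (vessel network) phantom
#'
#' Renders `vessel_count` smooth tubes with piecewise-linear centerlines and
#' per-tube radii drawn from `radius_range`. Tube cross-sections use a
#' distance-to-centerline profile with a 1-voxel soft edge (partial-volume
#' antialiasing), so boundaries are smooth enough for curvature-based
#' analysis. The first tube is always straight and aligned with the rotation
#' axis through the grid centre. Voxel values blend background and vessel
#' intensity by edge coverage.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_image()].
#' @export
make_vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  cov <- array(0, shape)     # max coverage over tubes (partial volume)
  lum <- array(0, shape)     # max of per-tube intensity * coverage
  overlap_hits <- 0L
  tube_voxels <- 0L
  withr::with_seed(spec$seed, {
    for (v in seq_len(spec$vessel_count)) {
      radius <- runif(1, spec$radius_range[1], spec$radius_range[2])
      inten <- spec$vessel_intensity *
        runif(1, spec$intensity_range[1], spec$intensity_range[2])
      if (v == 1L) {
        # guaranteed straight, axis-aligned tube (rotation axis)
        cxy <- (shape[1:2] + 1) / 2
        pts <- rbind(c(cxy, 1), c(cxy, shape[3]))
      } else {
        pts <- random_centerline(shape)
      }
      tube_cov <- array(0, shape)
      for (s in seq_len(nrow(pts) - 1L)) {
        sd_ <- segment_distance(shape, pts[s, ], pts[s + 1L, ], radius + 1)
        if (is.null(sd_)) next
        c_new <- pmin(1, pmax(0, radius + 0.5 - sd_$dist))
        tube_cov[sd_$idx] <- pmax(tube_cov[sd_$idx], c_new)
      }
      core_new <- tube_cov > 0.5
      core_old <- cov > 0.5
      overlap_hits <- overlap_hits + sum(core_new & core_old)
      tube_voxels <- tube_voxels + sum(core_new)
      cov <- pmax(cov, tube_cov)
      lum <- pmax(lum, inten * tube_cov)
    }
  })
  if (tube_voxels > 0 && overlap_hits / tube_voxels > 0.5)
    warning(sprintf("make_vessel_phantom: overlapping-volume fraction %.2f exceeds 0.5",
                    overlap_hits / tube_voxels))
  vals <- spec$background_intensity * (1 - cov) + lum
  volume_image(vals, voxel_size = spec$voxel_size)
}

# soft-edged ellipsoid coverage field added onto `vals`; edge_width in voxels
add_ellipsoid <- function(vals, shape, center, semi_axes, intensity,
                          edge_width = 1) {
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(semi_axes <= 0)) abort("ellipsoid semi-axes must be > 0")
  if (any(center - semi_axes < 0.5) || any(center + semi_axes > shape + 0.5))
    warning("anatomy ellipsoid extends outside the grid; clipped")
  lo <- floor(center - semi_axes - edge_width - 1)
  hi <- ceiling(center + semi_axes + edge_width + 1)
  lo <- pmax(1L, lo); hi <- pmin(shape, hi)
  if (any(lo > hi)) return(vals)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  x <- rep(gx, times = length(gy) * length(gz))
  y <- rep(rep(gy, each = length(gx)), times = length(gz))
  z <- rep(gz, each = length(gx) * length(gy))
  rho <- sqrt(((x - center[1]) / semi_axes[1])^2 +
              ((y - center[2]) / semi_axes[2])^2 +
              ((z - center[3]) / semi_axes[3])^2)
  # signed distance to the surface, approximated radially
  r_eff <- min(semi_axes)
  covg <- pmin(1, pmax(0, 0.5 + (1 - rho) * r_eff / edge_width))
  idx <- x + (y - 1) * shape[1] + (z - 1) * shape[1] * shape[2]
  vals[idx] <- vals[idx] + intensity * covg
  vals
}

#' Generate the transmission (anatomy) phantom
#'
#' Renders the spec's ellipsoids additively at their intensities over a
#' smooth low-contrast body envelope at `background_intensity`. Ellipsoids
#' reaching outside the grid are clipped with a warning.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_image()] of attenuation-scale values.
#' @export
make_anatomy_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  vals <- array(0, shape)
  if (spec$background_intensity > 0) {
    # smooth body envelope: soft ellipsoid covering ~80% of the grid
    vals <- add_ellipsoid(vals, shape, center = (shape + 1) / 2,
                          semi_axes = 0.40 * shape,
                          intensity = spec$background_intensity,
                          edge_width = 3)
  }
  for (b in spec$anatomy_blobs) {
    vals <- add_ellipsoid(vals, shape, b$center, b$semi_axes, b$intensity)
  }
  volume_image(vals, voxel_size = spec$voxel_size)
}

#' Simulate a two-channel projection acquisition
#'
#' Forward-projects every transaxial slice of the fluorescence and anatomy
#' volumes at every angle of the geometry and adds i.i.d. zero-mean Gaussian
#' noise of standard deviation `noise_sd` (an additive read-noise model; the
#' level is a free parameter). Both returned stacks are in the linear
#' line-integral domain and carry their geometry, seed and noise metadata.
#'
#' @param fluor fluorescence [volume_image()].
#' @param anat anatomy [volume_image()] of identical shape.
#' @param geom a [projection_geometry()] with evenly spaced angles.
#' @param noise_sd non-negative noise standard deviation; a scalar applies
#'   to both channels, a length-2 vector `(fluorescence, transmission)`
#'   sets each channel separately (the two channels record different
#'   physical quantities on different scales, so their read-noise levels
#'   are independent).
#' @param seed integer RNG seed for the noise.
#' @return named list with [projection_stack()] elements `fluorescence` and
#'   `transmission`.
#' @export
simulate_dataset <- function(fluor, anat, geom, noise_sd = 0, seed = 1L) {
  if (!identical(dim(fluor), dim(anat)))
    abort("simulate_dataset: volumes must share one shape")
  if (!is.numeric(noise_sd) || !length(noise_sd) %in% c(1L, 2L) ||
      anyNA(noise_sd) || min(noise_sd) < 0)
    abort("simulate_dataset: noise_sd must be non-negative (scalar or length 2)")
  noise_sd <- rep_len(noise_sd, 2L)
  d <- dim(fluor)
  if (d[1] != d[2])
    abort("simulate_dataset: slices must be square (pad upstream)")
  ang <- geom$angles_deg
  if (length(ang) > 2) {
    steps <- diff(ang)
    if (max(abs(steps - steps[1])) > 1e-6)
      abort("simulate_dataset: geometry angles must be evenly spaced")
  }
  A <- radon_system_matrix(d[1], geom)
  project_volume <- function(vol) {
    y <- as.matrix(A %*% matrix(bare(vol), nrow = d[1] * d[2]))
    array(y, c(geom$n_detector, length(ang), d[3]))
  }
  yf <- project_volume(fluor)
  ya <- project_volume(anat)
  if (max(noise_sd) > 0) {
    withr::with_seed(as.integer(seed), {
      if (noise_sd[1] > 0) yf <- yf + rnorm(length(yf), sd = noise_sd[1])
      if (noise_sd[2] > 0) ya <- ya + rnorm(length(ya), sd = noise_sd[2])
    })
  }
  # [bin, angle, slice] -> [angle, bin, slice]
  perm <- function(a) aperm(a, c(2, 1, 3))
  list(
    fluorescence = projection_stack(perm(yf), geom, channel = "fluorescence",
                                    noise_sd = noise_sd[1], seed = as.integer(seed),
                                    source = "vessel-phantom"),
    transmission = projection_stack(perm(ya), geom,
                                    channel = "transmission-converted",
                                    noise_sd = noise_sd[2], seed = as.integer(seed),
                                    source = "anatomy-phantom")
  )
}
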