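# shared fixtures, all generated in code

# centred disk image with a 1-voxel partial-volume edge (the package's
# standard antialiased rendering)
disk_image <- function(side, radius, value = 1) {
  c0 <- (side - 1) / 2
  d <- sqrt(outer(0:(side - 1) - c0, 0:(side - 1) - c0,
                  function(i, j) i^2 + j^2))
  m <- pmin(1, pmax(0, radius + 0.5 - d)) * value
  dim(m) <- c(side, side)
  m
}

# the standard seeded vessel phantom used across reconstruction tests
std_vessel_spec <- function(shape = c(64, 64, 64), seed = 42L) {
  phantom_spec(shape = shape, seed = seed)
}

# a single straight axis-aligned tube of fixed radius, zero background
straight_tube_spec <- function(shape = c(48, 48, 48), radius = 3) {
  phantom_spec(shape = shape, vessel_count = 1,
               radius_range = c(radius, radius),
               background_intensity = 0, seed = 1L)
}

geom_for <- function(n_angles, n_detector) {
  projection_geometry(evenly_spaced_angles(n_angles), n_detector = n_detector)
}

# bare array view (drop classes/attributes)
unwrap <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
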