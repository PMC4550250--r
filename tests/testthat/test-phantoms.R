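test_that("vessel phantom renders the requested network", {
  # empty network: background everywhere
  empty <- make_vessel_phantom(phantom_spec(shape = c(16, 16, 16),
                                            vessel_count = 0,
                                            background_intensity = 0.3,
                                            seed = 1))
  expect_equal(unwrap(empty), array(0.3, c(16, 16, 16)))

  # one straight axis-aligned tube: a filled disk at the same in-plane
  # position in every slice, core value equal to vessel_intensity
  vol <- make_vessel_phantom(straight_tube_spec(radius = 3))
  d <- dim(vol)
  ctr <- (d[1:2] + 1) / 2
  core <- disk_image(d[1], 2.0) > 0   # strictly inside the radius-3 tube
  for (k in c(1, 17, 33, d[3])) {
    sl <- unwrap(vol)[, , k]
    expect_true(all(abs(sl[core] - 100) < 1e-9))
    # outside the dilated tube footprint everything is background
    far <- disk_image(d[1], 5) == 0
    expect_true(all(sl[far] == 0))
  }
  # partial-volume soft edge: some voxels strictly between 0 and 100
  expect_true(any(unwrap(vol) > 1 & unwrap(vol) < 99))
})

test_that("phantom generation is a pure function of the spec", {
  spec <- std_vessel_spec(shape = c(24, 24, 24), seed = 7L)
  expect_identical(unwrap(make_vessel_phantom(spec)),
                   unwrap(make_vessel_phantom(spec)))
  expect_identical(unwrap(make_anatomy_phantom(spec)),
                   unwrap(make_anatomy_phantom(spec)))
  # a different seed changes the (random part of the) network
  spec2 <- std_vessel_spec(shape = c(24, 24, 24), seed = 8L)
  expect_false(identical(unwrap(make_vessel_phantom(spec)),
                         unwrap(make_vessel_phantom(spec2))))
})

test_that("phantom spec enforces the resolution floor and radius cap", {
  expect_error(phantom_spec(radius_range = c(1.0, 3)), "1.5-voxel")
  expect_error(phantom_spec(shape = c(16, 16, 16), radius_range = c(1.5, 8)),
               "min\\(shape\\)/4")
})

test_that("anatomy phantom has analytic volume and is additive", {
  shape <- c(48, 48, 48)
  # no blobs, zero background: all-zero volume
  zero <- make_anatomy_phantom(phantom_spec(shape = shape, anatomy_blobs = list(),
                                            background_intensity = 0, seed = 1))
  expect_equal(unwrap(zero), array(0, shape))

  # single centred sphere: voxel sum matches (4/3) pi r^3 within 2%
  r <- 10; a <- 0.7
  one <- make_anatomy_phantom(phantom_spec(
    shape = shape, background_intensity = 0, seed = 1,
    anatomy_blobs = list(list(center = c(24.5, 24.5, 24.5),
                              semi_axes = rep(r, 3), intensity = a))))
  expect_equal(sum(one), a * 4 / 3 * pi * r^3, tolerance = 0.02)

  # two blobs with disjoint support render additively
  b1 <- list(center = c(14, 14, 14), semi_axes = rep(5, 3), intensity = 1)
  b2 <- list(center = c(34, 34, 34), semi_axes = rep(5, 3), intensity = 2)
  both <- make_anatomy_phantom(phantom_spec(shape = shape,
                                            background_intensity = 0, seed = 1,
                                            anatomy_blobs = list(b1, b2)))
  each <- lapply(list(b1, b2), function(b)
    make_anatomy_phantom(phantom_spec(shape = shape, background_intensity = 0,
                                      seed = 1, anatomy_blobs = list(b))))
  expect_equal(unwrap(both), unwrap(each[[1]]) + unwrap(each[[2]]),
               tolerance = 1e-12)

  # ellipsoid reaching outside the grid is clipped with a warning
  expect_warning(make_anatomy_phantom(phantom_spec(
    shape = c(16, 16, 16), background_intensity = 0, seed = 1,
    anatomy_blobs = list(list(center = c(2, 8, 8), semi_axes = rep(4, 3),
                              intensity = 1)))), "clipped")
})

test_that("default phantoms satisfy the contrast invariants", {
  spec <- std_vessel_spec(shape = c(48, 48, 48))
  vol <- make_vessel_phantom(spec)
  # bimodal voxel histogram: background and vessel modes far apart relative
  # to the default 2%-of-peak noise level
  noise_sd <- 0.02 * max(vol)
  expect_gte(max(vol) - spec$background_intensity, 5 * noise_sd)
  expect_true(sum(unwrap(vol) > 50) > 0 && sum(unwrap(vol) < 1) > 0)

  # anatomy max intensity at least 5x the body-envelope level
  anat <- make_anatomy_phantom(spec)
  expect_gte(max(anat), 5 * spec$background_intensity)
})

test_that("simulated projections follow the additive-noise forward model", {
  shape <- c(24, 24, 24)
  spec <- std_vessel_spec(shape = shape, seed = 3L)
  fluor <- make_vessel_phantom(spec)
  anat <- make_anatomy_phantom(spec)
  geom <- geom_for(20, 24)

  # zero volumes, zero noise: all-zero stacks
  z <- volume_image(array(0, shape))
  sim0 <- simulate_dataset(z, z, geom, noise_sd = 0)
  expect_equal(max(abs(sim0$fluorescence$values)), 0)
  expect_equal(max(abs(sim0$transmission$values)), 0)

  # noiseless stack equals per-slice forward projections exactly
  sim <- simulate_dataset(fluor, anat, geom, noise_sd = 0)
  for (k in c(1, 12, 24)) {
    expect_equal(sim$fluorescence$values[, , k],
                 radon_forward(get_slice(fluor, k), geom)$values,
                 tolerance = 1e-12)
  }

  # noise moments: residual against the noiseless stack has mean ~ 0 and
  # sd ~ noise_sd (law of large numbers at >= 1e5 samples)
  geom_big <- geom_for(180, 24)
  noiseless <- simulate_dataset(fluor, anat, geom_big, noise_sd = 0)
  noisy <- simulate_dataset(fluor, anat, geom_big, noise_sd = 5, seed = 11L)
  res <- as.numeric(noisy$fluorescence$values - noiseless$fluorescence$values)
  expect_gte(length(res), 1e5)
  expect_lt(abs(mean(res)), 5 * 0.05)
  expect_equal(sd(res), 5, tolerance = 0.05)

  # determinism and error handling
  noisy2 <- simulate_dataset(fluor, anat, geom_big, noise_sd = 5, seed = 11L)
  expect_identical(noisy$fluorescence$values, noisy2$fluorescence$values)
  expect_error(simulate_dataset(fluor, volume_image(array(0, c(8, 8, 8))), geom),
               "share one shape")
  expect_error(simulate_dataset(fluor, anat, geom, noise_sd = -1),
               "non-negative")
})
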