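test_that("TV functional matches its definition", {
  expect_equal(tv_functional(matrix(7, 9, 9)), 0)

  # single vertical step of height h between two constant halves: m * h
  m <- 12; h <- 3.5
  step <- cbind(matrix(0, m, 6), matrix(h, m, 6))
  expect_equal(tv_functional(step), m * h)

  # brute-force per-pixel loop oracle on a random image
  set.seed(7)
  img <- matrix(rnorm(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) {
    dh <- if (j < 8) img[i, j + 1] - img[i, j] else 0
    dv <- if (i < 8) img[i + 1, j] - img[i, j] else 0
    acc <- acc + sqrt(dh^2 + dv^2)
  }
  expect_equal(tv_functional(img), acc, tolerance = 1e-12)
})

test_that("Chambolle denoiser contracts TV and vanishes with tau", {
  const <- matrix(3, 16, 16)
  expect_equal(tv_denoise(const, tau = 5, iters = 10), const)

  set.seed(8)
  noisy <- matrix(rnorm(32 * 32), 32, 32)
  tiny <- tv_denoise(noisy, tau = 1e-8, iters = 40)
  expect_equal(tiny, noisy, tolerance = 1e-4)

  # denoising a noisy step: closer to the clean step, TV at least halved
  clean <- cbind(matrix(0, 32, 16), matrix(100, 32, 16))
  corrupted <- clean + matrix(rnorm(32 * 32, sd = 10), 32, 32)
  den <- tv_denoise(corrupted, tau = 5, iters = 40)
  expect_lt(mean((den - clean)^2), mean((corrupted - clean)^2))
  expect_lte(tv_functional(den), 0.5 * tv_functional(corrupted))

  # TV never increases, for a spread of weights
  for (tau in c(0.1, 1, 10)) {
    expect_lte(tv_functional(tv_denoise(corrupted, tau, 20)),
               tv_functional(corrupted))
  }
  expect_error(tv_denoise(noisy, tau = 0), "positive")
})

test_that("the reconstruction objective composes its two terms", {
  geom <- geom_for(10, 16)
  zero_s <- sinogram(matrix(0, 10, 16), geom)
  expect_equal(objective(matrix(0, 16, 16), zero_s, geom, 0.01), 0)

  set.seed(9)
  y <- matrix(rnorm(10 * 16), 10, 16)
  ys <- sinogram(y, geom)
  expect_equal(objective(matrix(0, 16, 16), ys, geom, 0.01),
               0.5 * sum(y^2))

  x <- matrix(runif(256), 16, 16)
  direct <- 0.5 * sum((y - radon_forward(x, geom)$values)^2) +
    0.013 * tv_functional(x)
  expect_equal(objective(x, ys, geom, 0.013), direct, tolerance = 1e-9)
})

test_that("TwIST parameter validation enforces the stability range", {
  p <- twist_params()
  expect_gt(p$alpha, 0); expect_lt(p$alpha, 2)
  expect_gt(p$beta, 0)
  expect_error(twist_params(tau = 0), "positive")
  expect_error(twist_params(alpha = 2.1, beta = 1), "alpha")
  expect_error(twist_params(alpha = 1, beta = -1), "beta")
})

test_that("TwIST solves the zero problem immediately and descends monotonically", {
  geom <- geom_for(12, 16)
  zero_s <- sinogram(matrix(0, 12, 16), geom)
  res <- twist_reconstruct(zero_s, geom,
                           twist_params(init_mode = "zero", max_outer_iters = 5))
  expect_equal(max(abs(unwrap(res$image))), 0)
  expect_equal(res$iterations_run, 1L)

  # a noisy sparse-view problem: trace non-increasing, final <= first
  vol <- make_vessel_phantom(std_vessel_spec())
  sl <- unwrap(get_slice(vol, 20))
  g30 <- geom_for(30, 64)
  set.seed(10)
  noisy <- sinogram(radon_forward(sl, g30)$values +
                      rnorm(30 * 64, sd = 2), g30)
  for (init in c("backproject", "zero", "fbp")) {
    res <- twist_reconstruct(noisy, g30,
                             twist_params(tau = 0.006, tv_iters = 10,
                                          max_outer_iters = 30,
                                          init_mode = init))
    expect_true(all(diff(res$objective_trace) <= 1e-9 * res$objective_trace[1]))
    expect_lte(tail(res$objective_trace, 1), res$objective_trace[1])
  }
})

test_that("TwIST beats FBP on sparse noiseless data", {
  vol <- make_vessel_phantom(std_vessel_spec())
  sl <- unwrap(get_slice(vol, 32))
  g50 <- geom_for(50, 64)
  sino <- radon_forward(sl, g50)
  tw <- twist_reconstruct(sino, g50, twist_params(tau = 0.01, tv_iters = 40))
  s_tw <- ssim_global(unwrap(tw$image), sl)
  s_fbp <- ssim_global(unwrap(fbp_reconstruct(sino)), sl)
  expect_gte(s_tw, 0.90)
  expect_gt(s_tw, s_fbp)
})

test_that("TwIST reconstruction is scale-homogeneous in the data", {
  img <- disk_image(24, 7)
  geom <- geom_for(20, 24)
  sino <- radon_forward(img, geom)
  p <- twist_params(tau = 0.01, tv_iters = 10, max_outer_iters = 15)
  r1 <- unwrap(twist_reconstruct(sino, geom, p)$image)
  r2 <- unwrap(twist_reconstruct(sinogram(sino$values * 41, geom), geom, p)$image)
  expect_equal(r2, 41 * r1, tolerance = 1e-10)
})

test_that("TwIST approaches the phantom as tau vanishes on dense data", {
  img <- disk_image(32, 9)
  geom <- geom_for(64, 32)
  sino <- radon_forward(img, geom)
  res <- twist_reconstruct(sino, geom,
                           twist_params(tau = 1e-5, tv_iters = 5,
                                        max_outer_iters = 200, rel_tol = 0))
  expect_gte(ssim_global(unwrap(res$image), img), 0.99)
})

test_that("volume TwIST composes slice reconstructions", {
  spec <- std_vessel_spec(shape = c(16, 16, 16), seed = 6L)
  # zero stack reconstructs to the zero volume
  geom <- geom_for(12, 16)
  zstack <- projection_stack(array(0, c(12, 16, 3)), geom)
  p <- twist_params(tv_iters = 5, max_outer_iters = 5, init_mode = "zero")
  expect_equal(max(abs(twist_volume(zstack, p))), 0)

  vol <- make_vessel_phantom(phantom_spec(shape = c(16, 16, 16),
                                          vessel_count = 2,
                                          radius_range = c(1.5, 2),
                                          seed = 6L))
  sim <- simulate_dataset(vol, vol, geom)
  p2 <- twist_params(tau = 0.01, tv_iters = 5, max_outer_iters = 10)
  rv <- twist_volume(sim$fluorescence, p2)
  traces <- attr(rv, "objective_traces")
  expect_length(traces, 16)
  for (k in c(1, 9)) {
    ind <- twist_reconstruct(get_sinogram(sim$fluorescence, k),
                             sim$fluorescence$geometry, p2)
    sl <- unwrap(ind$image); sl[sl < 0] <- 0
    expect_equal(unwrap(rv)[, , k], sl, tolerance = 1e-12)
    expect_equal(traces[[k]], ind$objective_trace)
  }
})
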