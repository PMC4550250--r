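test_that("scale-normalised Hessian differentiates exactly on polynomials", {
  # constant volume: zero Hessian
  h0 <- hessian_at_scale(array(5, c(12, 12, 12)), 1.5)
  for (cmp in c("xx", "yy", "zz", "xy", "xz", "yz"))
    expect_equal(max(abs(h0[[cmp]])), 0, tolerance = 1e-12)

  # separable quadratic along axis 1: d2/dx2 = 2, gamma-normalised 2 sigma^2
  n <- 33; sg <- 2.5
  vol <- array(rep((1:n - 17)^2, n * n), c(n, n, n))
  h <- hessian_at_scale(vol, sg)
  mid <- 12:22
  expect_equal(h$xx[mid, mid, mid], array(2 * sg^2, c(11, 11, 11)),
               tolerance = 1e-6)
  expect_lt(max(abs(h$yy[mid, mid, mid])), 1e-8)
  expect_lt(max(abs(h$xy[mid, mid, mid])), 1e-8)

  expect_error(hessian_at_scale(vol, 0.4), ">= 0.5")
  expect_error(hessian_at_scale(array(0, c(4, 4, 4)), 20), "too large")
})

test_that("separable Hessian equals direct 3-D convolution", {
  set.seed(11)
  vol <- array(runif(16^3), c(16, 16, 16))
  sg <- 1
  h <- hessian_at_scale(vol, sg)
  k <- optomo:::gaussian_kernels(sg)
  r <- k$radius
  # oracle: brute-force correlation with the full outer-product 3-D kernel
  # over a reflectively padded copy
  pad <- vol[optomo:::reflect_idx(16, r), , ][, optomo:::reflect_idx(16, r), ]
  pad <- pad[, , optomo:::reflect_idx(16, r)]
  direct <- function(k1, k2, k3) {
    kern <- outer(outer(k1, k2), k3)
    out <- array(0, c(16, 16, 16))
    for (a in seq_len(2 * r + 1)) for (b in seq_len(2 * r + 1))
      for (cc in seq_len(2 * r + 1)) {
        out <- out + kern[a, b, cc] *
          pad[a:(a + 15), b:(b + 15), cc:(cc + 15)]
      }
    out
  }
  expect_equal(h$xx, sg^2 * direct(k$g2, k$g0, k$g0), tolerance = 1e-6)
  expect_equal(h$yz, sg^2 * direct(k$g0, k$g1, k$g1), tolerance = 1e-6)
})

test_that("eigen-triples are ordered by magnitude and algebraically exact", {
  expect_equal(unname(eigen_sorted(diag(c(0, -2, -2)))), c(0, -2, -2))
  expect_equal(unname(eigen_sorted(diag(3) * 5)), c(5, 5, 5))
  expect_error(eigen_sorted(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3)),
               "symmetric")
  expect_error(eigen_sorted(c(1, NA, 3, 4, 5, 6)), "finite")

  set.seed(12)
  for (i in 1:1000) {
    m <- matrix(rnorm(9), 3); m <- (m + t(m)) / 2
    ev <- unname(eigen_sorted(m))
    expect_true(abs(ev[1]) <= abs(ev[2]) + 1e-12 &&
                  abs(ev[2]) <= abs(ev[3]) + 1e-12)
    # characteristic polynomial: eigenvalues reproduce trace, minor sum, det
    expect_equal(sum(ev), sum(diag(m)), tolerance = 1e-8)
    expect_equal(prod(ev), det(m), tolerance = 1e-8)
    minors <- m[1,1]*m[2,2] - m[1,2]^2 + m[1,1]*m[3,3] - m[1,3]^2 +
      m[2,2]*m[3,3] - m[2,3]^2
    expect_equal(ev[1]*ev[2] + ev[1]*ev[3] + ev[2]*ev[3], unname(minors),
                 tolerance = 1e-8)
  }
})

test_that("vesselness closed forms discriminate tubes, spheres and plates", {
  p <- vesselness_params()          # a = b = 0.5, c = 500
  L <- 1e5                          # S >> c: background factor saturates
  expect_equal(vesselness_at_voxel(c(0, -L, -L), p), 1 - exp(-2),
               tolerance = 1e-6)
  expect_equal(vesselness_at_voxel(c(-L, -L, -L), p),
               (1 - exp(-2)) * exp(-2), tolerance = 1e-6)
  expect_equal(vesselness_at_voxel(c(0, 0, -L), p), 0)       # plate
  expect_equal(vesselness_at_voxel(c(0, 1, -5), p), 0)       # lambda2 > 0
  expect_equal(vesselness_at_voxel(c(0, -1, 5), p), 0)       # lambda3 > 0
  expect_equal(vesselness_at_voxel(c(0, 0, 0), p), 0)        # degenerate
  # dark polarity mirrors the signs
  pd <- vesselness_params(polarity = "dark")
  expect_equal(vesselness_at_voxel(c(0, L, L), pd), 1 - exp(-2),
               tolerance = 1e-6)
  expect_equal(vesselness_at_voxel(c(0, -L, -L), pd), 0)
})

test_that("multiscale vesselness finds the tube at its natural scale", {
  vol <- make_vessel_phantom(straight_tube_spec(radius = 3))
  p <- vesselness_params()
  vm <- vesselness_multiscale(vol, p)
  expect_true(all(vm$values >= 0 & vm$values <= 1))

  # constant volume: all-zero map
  flat <- vesselness_multiscale(array(2, c(16, 16, 16)),
                                vesselness_params(sigma_max = 3, n_scales = 3))
  expect_equal(max(flat$values), 0)

  # centerline response dominates background
  ctr <- 24
  cl <- vm$values[ctr, ctr, 10:38]
  bg <- vm$values[4:10, 4:10, 5:43]
  expect_gte(median(cl), 5 * quantile(bg, 0.95))

  # maximising scale within one scale step of r / sqrt(2)
  sg_best <- median(vm$best_sigma[ctr, ctr, 10:38])
  target <- 3 / sqrt(2)
  steps <- vm$scales
  nearest <- which.min(abs(steps - target))
  expect_true(sg_best %in% steps[pmax(1, nearest - 1):pmin(length(steps), nearest + 1)])

  # n_scales = 1 equals the single-scale field, cross-checked per voxel
  # against the scalar closed-form path
  p1 <- vesselness_params(sigma_min = 2, sigma_max = 2, n_scales = 1)
  vm1 <- vesselness_multiscale(vol, p1)
  h <- hessian_at_scale(vol, 2)
  for (vx in list(c(24, 24, 20), c(24, 26, 20), c(10, 10, 10))) {
    e <- eigen_sorted(c(h$xx[vx[1], vx[2], vx[3]], h$yy[vx[1], vx[2], vx[3]],
                        h$zz[vx[1], vx[2], vx[3]], h$xy[vx[1], vx[2], vx[3]],
                        h$xz[vx[1], vx[2], vx[3]], h$yz[vx[1], vx[2], vx[3]]))
    expect_equal(vm1$values[vx[1], vx[2], vx[3]],
                 vesselness_at_voxel(e, p1), tolerance = 1e-10)
  }
})

test_that("vesselness is shift-invariant and contrast-monotone", {
  vol <- make_vessel_phantom(straight_tube_spec(shape = c(32, 32, 32),
                                                radius = 3))
  p <- vesselness_params(n_scales = 3)
  v1 <- vesselness_multiscale(vol, p)$values
  v2 <- vesselness_multiscale(unwrap(vol) + 37, p)$values
  expect_equal(v1, v2, tolerance = 1e-8)

  # S << c regime: scaling intensities up never decreases vesselness
  v3 <- vesselness_multiscale(unwrap(vol) * 3, p)$values
  expect_true(all(v3 - v1 >= -1e-10))
})

test_that("mask extraction recovers the tube support", {
  vol <- make_vessel_phantom(straight_tube_spec(radius = 3))
  p <- vesselness_params()
  vm <- vesselness_multiscale(vol, p)
  mask <- segment_mask(vm, p)
  truth <- unwrap(vol) > 50
  dil <- optomo:::dilate6(truth)
  recall <- sum(mask & truth) / sum(truth)
  precision <- sum(mask & dil) / sum(mask)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)
  expect_true(is.numeric(attr(mask, "threshold")))

  # fixed threshold on a binary map keeps exactly the support of the ones
  toy <- array(0, c(4, 4, 4)); toy[1:2, 1, 1] <- 1
  pm <- vesselness_params(mask_threshold = 0.5)
  expect_equal(segment_mask(toy, pm) & TRUE, toy > 0.5)

  # all-zero map: empty mask with a warning under the otsu policy
  expect_warning(m0 <- segment_mask(array(0, c(4, 4, 4)), p), "empty mask")
  expect_equal(sum(m0), 0)
})
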