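#' Vesselness filter parameters
#'
#' Sensitivity thresholds and scale schedule for the multiscale
#' Hessian-based vesselness measure. `a` controls the tube-vs-plate ratio,
#' `b` the tube-vs-blob ratio and `c` the structure-vs-background norm;
#' defaults `a = b = 0.5`, `c = 500`. Scales are sampled log-uniformly from
#' `sigma_min` to `sigma_max` (voxels); a tube of radius `r` responds most
#' strongly near `sigma = r / sqrt(2)`.
#'
#' @param a,b,c positive sensitivity thresholds.
#' @param sigma_min,sigma_max scale range in voxels (`sigma_min >= 0.5`).
#' @param n_scales number of scales (>= 1).
#' @param polarity `"bright"` for bright tubes on dark background (the
#'   fluorescence case), `"dark"` for the reverse.
#' @param mask_threshold fixed threshold in (0, 1), or `"otsu"` to pick the
#'   threshold automatically on the positive vesselness values.
#' @return an object of class `vesselness_params`.
#' @export
vesselness_params <- function(a = 0.5, b = 0.5, c = 500,
                              sigma_min = 1, sigma_max = 6, n_scales = 5L,
                              polarity = c("bright", "dark"),
                              mask_threshold = "otsu") {
  polarity <- match.arg(polarity)
  stopifnot(is_scalar_num(a), a > 0, is_scalar_num(b), b > 0,
            is_scalar_num(c), c > 0,
            is_scalar_num(sigma_min), is_scalar_num(sigma_max),
            is_scalar_num(n_scales), n_scales >= 1)
  if (sigma_min < 0.5)
    abort("vesselness_params: sigma_min below 0.5 voxels is sub-grid")
  if (sigma_min > sigma_max)
    abort("vesselness_params: sigma_min must not exceed sigma_max")
  if (is.numeric(mask_threshold)) {
    if (mask_threshold <= 0 || mask_threshold >= 1)
      abort("vesselness_params: numeric mask_threshold must lie in (0, 1)")
  } else if (!identical(mask_threshold, "otsu")) {
    abort("vesselness_params: mask_threshold must be numeric or \"otsu\"")
  }
  structure(list(a = a, b = b, c = c,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 n_scales = as.integer(n_scales), polarity = polarity,
                 mask_threshold = mask_threshold),
            class = "vesselness_params")
}

# sampled Gaussian kernel and its first/second derivatives, moment-corrected
# so that responses to 1, x and x^2/2 are exactly 0/±1/1 (order-true filters)
gaussian_kernels <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- (-r):r
  g0 <- exp(-x^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  g1 <- -x / sigma^2 * exp(-x^2 / (2 * sigma^2))
  g1 <- g1 - mean(g1)                       # zero response to constants
  s1 <- sum(g1 * (-x))                      # correlation response to f(x)=x
  g1 <- g1 / s1
  g2 <- (x^2 / sigma^2 - 1) / sigma^2 * exp(-x^2 / (2 * sigma^2))
  g2 <- g2 - mean(g2)                       # zero response to constants
  g2 <- g2 - g1 * sum(g2 * (-x))            # zero response to linear ramps
  g2 <- g2 * (2 / sum(g2 * x^2))            # unit response to x^2 -> 2
  list(g0 = g0, g1 = g1, g2 = g2, radius = r)
}

# correlate a 3-D array with a 1-D kernel along `axis`, reflective padding
conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  r <- (length(kern) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  n <- d[axis]
  mat <- matrix(ap, nrow = n)
  pad <- mat[reflect_idx(n, r), , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (m in seq_along(kern)) {
    if (kern[m] != 0)
      out <- out + kern[m] * pad[m:(m + n - 1L), , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Scale-normalised Hessian field of a volume
#'
#' Second derivatives of the volume after Gaussian smoothing at scale
#' `sigma`, computed by separable correlation with sampled
#' Gaussian-derivative kernels (reflective boundary) and multiplied by
#' `sigma^2` (gamma-normalisation, so structures of different sizes compete
#' fairly across scales).
#'
#' @param volume a [volume_image()] or 3-D array.
#' @param sigma Gaussian scale in voxels (>= 0.5, and small enough that the
#'   kernel fits the grid).
#' @return an object of class `hessian_field`: list of six arrays
#'   `xx, yy, zz, xy, xz, yz` (axis 1 = x here) plus the scale.
#' @export
hessian_at_scale <- function(volume, sigma) {
  vol <- bare(volume)
  if (length(dim(vol)) != 3L) abort("hessian_at_scale: need a 3-D volume")
  if (!is_scalar_num(sigma) || sigma < 0.5)
    abort("hessian_at_scale: sigma must be >= 0.5 voxels")
  k <- gaussian_kernels(sigma)
  if (k$radius > min(dim(vol)))   # reflective padding needs radius <= side
    abort("hessian_at_scale: sigma %.3g too large for a %s grid",
          sigma, paste(dim(vol), collapse = "x"))
  s2 <- sigma^2
  # smooth once per axis where only smoothing is needed, reuse aggressively
  s1v <- conv_axis(vol, k$g0, 1)   # smoothed along axis 1
  s2v <- conv_axis(vol, k$g0, 2)
  s12 <- conv_axis(s1v, k$g0, 2)   # smoothed along axes 1 and 2
  h <- list(
    xx = s2 * conv_axis(conv_axis(s2v, k$g0, 3), k$g2, 1),
    yy = s2 * conv_axis(conv_axis(s1v, k$g0, 3), k$g2, 2),
    zz = s2 * conv_axis(s12, k$g2, 3),
    xy = s2 * conv_axis(conv_axis(conv_axis(vol, k$g1, 1), k$g1, 2), k$g0, 3),
    xz = s2 * conv_axis(conv_axis(conv_axis(vol, k$g1, 1), k$g0, 2), k$g1, 3),
    yz = s2 * conv_axis(conv_axis(conv_axis(vol, k$g0, 1), k$g1, 2), k$g1, 3)
  )
  structure(c(h, list(sigma = sigma)), class = "hessian_field")
}

# vectorised eigenvalues of symmetric 3x3 matrices given component vectors;
# returns a 3-column matrix ordered by |.| ascending per row
eigen3_sym <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  n <- length(xx)
  e1 <- e2 <- e3 <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx[nz] - q[nz]) / p[nz]; byy <- (yy[nz] - q[nz]) / p[nz]
    bzz <- (zz[nz] - q[nz]) / p[nz]
    bxy <- xy[nz] / p[nz]; bxz <- xz[nz] / p[nz]; byz <- yz[nz] / p[nz]
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
            bxz * (bxy * byz - byy * bxz)
    r <- pmin(1, pmax(-1, detb / 2))
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)                  # largest algebraic
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)     # smallest algebraic
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  ev <- cbind(e1, e2, e3)
  # sorting network on |.| (three pairwise exchanges)
  for (pair in list(c(1L, 2L), c(2L, 3L), c(1L, 2L))) {
    i <- pair[1]; j <- pair[2]
    swap <- abs(ev[, i]) > abs(ev[, j])
    if (any(swap)) {
      tmp <- ev[swap, i]
      ev[swap, i] <- ev[swap, j]
      ev[swap, j] <- tmp
    }
  }
  colnames(ev) <- c("l1", "l2", "l3")
  ev
}

#' Eigenvalues of a symmetric 3x3 Hessian, ordered by magnitude
#'
#' Returns the eigen-triple `(l1, l2, l3)` with `|l1| <= |l2| <= |l3|`, the
#' ordering the vesselness ratios are built on.
#'
#' @param h either a symmetric 3x3 numeric matrix, or a numeric vector of
#'   the six components `(xx, yy, zz, xy, xz, yz)`.
#' @return named numeric vector `c(l1, l2, l3)`.
#' @examples
#' eigen_sorted(diag(c(0, -2, -2)))  # 0, -2, -2
#' @export
eigen_sorted <- function(h) {
  if (is.matrix(h)) {
    if (!all(dim(h) == c(3L, 3L)) || max(abs(h - t(h))) > 1e-8 * (1 + max(abs(h))))
      abort("eigen_sorted: need a symmetric 3x3 matrix")
    comp <- c(h[1, 1], h[2, 2], h[3, 3], h[1, 2], h[1, 3], h[2, 3])
  } else {
    if (length(h) != 6L) abort("eigen_sorted: need 6 components (xx, yy, zz, xy, xz, yz)")
    comp <- as.numeric(h)
  }
  if (!all(is.finite(comp))) abort("eigen_sorted: non-finite input")
  ev <- eigen3_sym(comp[1], comp[2], comp[3], comp[4], comp[5], comp[6])
  c(l1 = ev[1, 1], l2 = ev[1, 2], l3 = ev[1, 3])
}

# vectorised vesselness from ordered eigenvalue columns
vesselness_from_eigen <- function(l1, l2, l3, p) {
  if (p$polarity == "dark") {
    l1 <- -l1; l2 <- -l2; l3 <- -l3
  }
  v <- numeric(length(l1))
  ok <- !(l2 > 0 | l3 > 0) & l3 != 0
  if (any(ok)) {
    a1 <- abs(l1[ok]); a2 <- abs(l2[ok]); a3 <- abs(l3[ok])
    ra <- a2 / a3
    rb <- a1 / sqrt(a2 * a3)
    rb[a2 == 0] <- 0                      # l1 = l2 = 0: ideal line limit
    s <- sqrt(l1[ok]^2 + l2[ok]^2 + l3[ok]^2)
    v[ok] <- (1 - exp(-ra^2 / (2 * p$a^2))) *
             exp(-rb^2 / (2 * p$b^2)) *
             (1 - exp(-s^2 / (2 * p$c^2)))
  }
  v
}

#' Vesselness of one eigen-triple
#'
#' The tube-likelihood score in `[0, 1]`: zero whenever `l2 > 0` or
#' `l3 > 0` (for bright polarity; signs mirrored for dark), otherwise
#' `(1 - exp(-Ra^2 / 2a^2)) * exp(-Rb^2 / 2b^2) * (1 - exp(-S^2 / 2c^2))`
#' with `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and
#' `S = sqrt(l1^2 + l2^2 + l3^2)`. Degenerate triples (`l3 = 0`) map to 0.
#'
#' @param e eigen-triple ordered by magnitude (as from [eigen_sorted()]).
#' @param p a [vesselness_params()].
#' @return scalar in `[0, 1]`.
#' @examples
#' vesselness_at_voxel(c(0, -1000, -1000), vesselness_params())  # ~ 1 - exp(-2)
#' @export
vesselness_at_voxel <- function(e, p = vesselness_params()) {
  stopifnot(length(e) == 3L, all(is.finite(e)), inherits(p, "vesselness_params"))
  vesselness_from_eigen(e[1], e[2], e[3], p)
}

#' Multiscale vesselness map of a volume
#'
#' Voxelwise maximum of the single-scale vesselness over `n_scales` scales
#' sampled log-uniformly between `sigma_min` and `sigma_max`. The winning
#' scale per voxel is returned alongside the map.
#'
#' @param volume a [volume_image()] or 3-D array.
#' @param p a [vesselness_params()].
#' @return an object of class `vesselness_map`: list with `values` (array
#'   in `[0, 1]`), `best_sigma` (array of argmax scales), `scales` and
#'   `params`.
#' @export
vesselness_multiscale <- function(volume, p = vesselness_params()) {
  vol <- bare(volume)
  if (length(dim(vol)) != 3L) abort("vesselness_multiscale: need a 3-D volume")
  stopifnot(inherits(p, "vesselness_params"))
  scales <- logspace(p$sigma_min, p$sigma_max, p$n_scales)
  best <- array(0, dim(vol))
  best_sigma <- array(scales[1], dim(vol))
  for (sg in scales) {
    h <- hessian_at_scale(vol, sg)
    ev <- eigen3_sym(as.numeric(h$xx), as.numeric(h$yy), as.numeric(h$zz),
                     as.numeric(h$xy), as.numeric(h$xz), as.numeric(h$yz))
    v <- array(vesselness_from_eigen(ev[, 1], ev[, 2], ev[, 3], p), dim(vol))
    gain <- v > best
    best[gain] <- v[gain]
    best_sigma[gain] <- sg
  }
  structure(list(values = best, best_sigma = best_sigma,
                 scales = scales, params = p),
            class = "vesselness_map")
}

#' @export
print.vesselness_map <- function(x, ...) {
  cat(sprintf("<vesselness_map> %s, %d scales in [%.3g, %.3g], max V = %.4f\n",
              paste(dim(x$values), collapse = "x"), length(x$scales),
              min(x$scales), max(x$scales), max(x$values)))
  invisible(x)
}

#' Binary vessel mask from a vesselness map
#'
#' Thresholds the vesselness map either at a fixed value in (0, 1) or, by
#' default, with Otsu's method computed in the log domain over the
#' supported vesselness values (those above 0.1% of the map peak).
#' Vesselness responses span several decades — the geometric (log) scale is
#' where their foreground/background modes are separable, and values below
#' a thousandth of the peak are numerically negligible background. The
#' policy is parameter-free and the threshold used is recorded on the
#' mask.
#'
#' @param map a [vesselness_map()] (or plain array in `[0, 1]`).
#' @param p a [vesselness_params()] carrying the threshold policy.
#' @return logical 3-D array with attribute `threshold`.
#' @export
segment_mask <- function(map, p = vesselness_params()) {
  vals <- if (inherits(map, "vesselness_map")) map$values else bare(map)
  stopifnot(inherits(p, "vesselness_params"))
  if (min(vals) < 0 || max(vals) > 1)
    abort("segment_mask: vesselness values must lie in [0, 1]")
  if (is.numeric(p$mask_threshold)) {
    thr <- p$mask_threshold
  } else {
    pos <- vals[vals >= 1e-3 * max(vals) & vals > 0]
    if (length(pos) == 0L) {
      warning("segment_mask: all-zero vesselness map; returning empty mask")
      thr <- 1
    } else {
      thr <- exp(otsu_threshold(log(pos)))
    }
  }
  mask <- vals >= thr & vals > 0
  attr(mask, "threshold") <- thr
  mask
}
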