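#' Filtered back projection parameters
#'
#' @param filter_name detector-domain frequency filter: `"ramp"` (Ram-Lak),
#'   `"shepp-logan"` or `"hamming"` windowed ramp.
#' @param pad_factor zero-padding multiple of the next power of two used for
#'   the FFT filtering (>= 1); padding suppresses circular-convolution
#'   wrap-around.
#' @param output_side side length of the reconstructed slice.
#' @return an object of class `fbp_params`.
#' @export
fbp_params <- function(filter_name = c("ramp", "shepp-logan", "hamming"),
                       pad_factor = 2L, output_side = NULL) {
  filter_name <- match.arg(filter_name)
  stopifnot(is_scalar_num(pad_factor), pad_factor >= 1)
  if (!is.null(output_side))
    stopifnot(is_scalar_num(output_side), output_side >= 1)
  structure(list(filter_name = filter_name,
                 pad_factor = as.integer(pad_factor),
                 output_side = if (is.null(output_side)) NULL
                               else as.integer(output_side)),
            class = "fbp_params")
}

# frequency response of the band-limited discrete ramp kernel
# (h[0] = 1/4, h[m] = -1/(pi^2 m^2) for odd m, 0 for even m), with the DC
# bin forced to exactly zero so constant rows are annihilated
ramp_frequency_response <- function(n, filter_name = "ramp") {
  m <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  h <- numeric(n)
  h[m == 0] <- 0.25
  odd <- (m %% 2) != 0
  h[odd] <- -1 / (pi^2 * m[odd]^2)
  f <- Re(stats::fft(h))
  f[f < 0] <- 0
  f[1] <- 0
  if (filter_name != "ramp") {
    # window in normalised frequency [0, 1]
    freq <- abs(m) / (n / 2)
    w <- switch(filter_name,
      "shepp-logan" = ifelse(freq == 0, 1, sin(pi * freq / 2) / (pi * freq / 2)),
      "hamming"     = 0.54 + 0.46 * cos(pi * freq),
      abort("ramp_frequency_response: unknown filter '%s'", filter_name))
    f <- f * w
  }
  f
}

#' Ramp-filter a sinogram
#'
#' Filters each detector row in the frequency domain with the chosen ramp
#' (optionally windowed) filter, zero-padding each row to
#' `pad_factor x` the next power of two. The filter's DC component is zero,
#' so constant rows are mapped to (numerically) zero.
#'
#' @param sino a [sinogram()].
#' @param params an [fbp_params()].
#' @return a [sinogram()] of filtered rows (same geometry and channel).
#' @export
ramp_filter <- function(sino, params = fbp_params()) {
  stopifnot(inherits(sino, "sinogram"), inherits(params, "fbp_params"))
  nd <- ncol(sino$values)
  if (nd < 2) abort("ramp_filter: need at least 2 detector bins")
  n_pad <- params$pad_factor * 2^ceiling(log2(nd))
  f <- ramp_frequency_response(n_pad, params$filter_name)
  padded <- matrix(0, nrow(sino$values), n_pad)
  padded[, seq_len(nd)] <- sino$values
  ft <- t(stats::mvfft(t(padded)))
  ft <- sweep(ft, 2, f, `*`)
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / n_pad
  sinogram(out[, seq_len(nd), drop = FALSE], sino$geometry,
           channel = sino$channel, slice_index = sino$slice_index)
}

#' Reconstruct one slice by filtered back projection
#'
#' Classic analytic reconstruction: frequency-domain ramp filtering of each
#' sinogram row followed by back projection, scaled by `pi / n_angles`
#' (the 180-degree-equivalent view count for full-rotation data, so the
#' redundant opposing rays average rather than double).
#'
#' @param sino a [sinogram()] with at least 2 angles.
#' @param params an [fbp_params()]; `output_side` defaults to `n_detector`.
#' @return a [slice_image()].
#' @examples
#' geom <- projection_geometry(evenly_spaced_angles(64), n_detector = 32)
#' img <- matrix(0, 32, 32); img[10:22, 10:22] <- 1
#' rec <- fbp_reconstruct(radon_forward(img, geom))
#' @export
fbp_reconstruct <- function(sino, params = fbp_params()) {
  stopifnot(inherits(sino, "sinogram"))
  n_ang <- nrow(sino$values)
  if (n_ang < 2)
    abort("fbp_reconstruct: reconstruction from a single angle is ill-posed")
  side <- if (is.null(params$output_side)) sino$geometry$n_detector
          else params$output_side
  if (side > sino$geometry$n_detector)
    abort("fbp_reconstruct: output_side exceeds n_detector")
  filtered <- ramp_filter(sino, params)
  bp <- back_project(filtered, side)
  pitch <- sino$geometry$detector_pitch
  slice_image(bare(bp) * pi / (n_ang * pitch^2),
              voxel_size = pitch)
}

#' Reconstruct a whole volume by FBP
#'
#' Applies [fbp_reconstruct()] to every slice of a projection stack and
#' assembles the slices along the rotation axis.
#'
#' @param stack a [projection_stack()].
#' @param params an [fbp_params()].
#' @return a [volume_image()]; negative reconstruction values are clipped
#'   to zero (physical non-negativity of the imaged quantities).
#' @export
fbp_volume <- function(stack, params = fbp_params()) {
  stopifnot(inherits(stack, "projection_stack"))
  ns <- n_slices(stack)
  if (ns < 1) abort("fbp_volume: empty stack")
  side <- if (is.null(params$output_side)) stack$geometry$n_detector
          else params$output_side
  out <- array(0, c(side, side, ns))
  for (k in seq_len(ns)) {
    out[, , k] <- bare(fbp_reconstruct(get_sinogram(stack, k), params))
  }
  out[out < 0] <- 0
  volume_image(out, voxel_size = stack$geometry$detector_pitch)
}
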