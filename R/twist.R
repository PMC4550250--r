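#' TwIST reconstruction parameters
#'
#' Controls for total-variation-regularised reconstruction by the two-step
#' iterative shrinkage/thresholding (TwIST) scheme with a Chambolle
#' dual-projection TV denoiser as the proximal step.
#'
#' The defaults for the two-step weights follow the reference TwIST rule for
#' an operator normalised to unit spectral norm, assuming a smallest-to-
#' largest eigenvalue ratio `xi = 1e-4` of the normal operator:
#' `rho = (1 - sqrt(xi)) / (1 + sqrt(xi))`, `alpha = 2 / (1 + sqrt(1 - rho^2))`,
#' `beta = 2 * alpha / (1 + xi)`. Note `beta > alpha` under this rule; the
#' scheme requires `0 < alpha < 2` and `beta > 0`, and a monotone safeguard
#' (see [twist_reconstruct()]) guarantees a non-increasing objective
#' regardless.
#'
#' @param tau positive dimensionless regularisation weight; the working
#'   weight is `tau` times the data's intensity scale (see
#'   [twist_reconstruct()]), so the same grid of values behaves alike at
#'   any recording scale.
#' @param tv_iters number of inner Chambolle iterations per denoising call
#'   (the TV iteration count knob; >= 1).
#' @param alpha,beta two-step weights; defaults per the rule above.
#' @param max_outer_iters outer iteration cap.
#' @param rel_tol relative objective-change stopping tolerance.
#' @param init_mode starting image: `"backproject"` (scaled back
#'   projection, default), `"zero"`, or `"fbp"`.
#' @param nonneg clamp iterates to be non-negative (off by default).
#' @return an object of class `twist_params`.
#' @export
twist_params <- function(tau = 0.01, tv_iters = 40L,
                         alpha = NULL, beta = NULL,
                         max_outer_iters = 100L, rel_tol = 1e-4,
                         init_mode = c("backproject", "zero", "fbp"),
                         nonneg = FALSE) {
  init_mode <- match.arg(init_mode)
  if (!is_scalar_num(tau) || tau <= 0)
    abort("twist_params: tau must be a positive scalar")
  stopifnot(is_scalar_num(tv_iters), tv_iters >= 1,
            is_scalar_num(max_outer_iters), max_outer_iters >= 1,
            is_scalar_num(rel_tol), rel_tol >= 0,
            is.logical(nonneg), length(nonneg) == 1L)
  if (is.null(alpha) || is.null(beta)) {
    xi <- 1e-4
    rho <- (1 - sqrt(xi)) / (1 + sqrt(xi))
    alpha <- 2 / (1 + sqrt(1 - rho^2))
    beta <- 2 * alpha / (1 + xi)
  }
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha >= 2)
    abort("twist_params: alpha must lie in (0, 2)")
  if (!is_scalar_num(beta) || beta <= 0)
    abort("twist_params: beta must be positive")
  structure(list(tau = tau, tv_iters = as.integer(tv_iters),
                 alpha = alpha, beta = beta,
                 max_outer_iters = as.integer(max_outer_iters),
                 rel_tol = rel_tol, init_mode = init_mode, nonneg = nonneg),
            class = "twist_params")
}

#' @export
print.twist_params <- function(x, ...) {
  cat(sprintf("<twist_params> tau %.4g, tv_iters %d, alpha %.4f, beta %.4f, max %d iters, rel_tol %.1e, init %s%s\n",
              x$tau, x$tv_iters, x$alpha, x$beta, x$max_outer_iters,
              x$rel_tol, x$init_mode, if (x$nonneg) ", nonneg" else ""))
  invisible(x)
}

# forward differences with replicate (zero-gradient) boundary on the last
# row/column; returns list(h = d/dcol, v = d/drow)
grad2 <- function(u) {
  n <- nrow(u); m <- ncol(u)
  gh <- matrix(0, n, m)
  gv <- matrix(0, n, m)
  if (m > 1) gh[, -m] <- u[, -1] - u[, -m]
  if (n > 1) gv[-n, ] <- u[-1, ] - u[-n, ]
  list(h = gh, v = gv)
}

# negative adjoint of grad2 (discrete divergence); the dual fields carry no
# component on the last row/column (their gradients there are zero)
div2 <- function(ph, pv) {
  n <- nrow(ph); m <- ncol(ph)
  dh <- ph
  if (m > 1) {
    dh[, 2:m] <- ph[, 2:m] - ph[, 1:(m - 1)]
    dh[, m] <- -ph[, m - 1]
  }
  dv <- pv
  if (n > 1) {
    dv[2:n, ] <- pv[2:n, ] - pv[1:(n - 1), ]
    dv[n, ] <- -pv[n - 1, ]
  }
  dh + dv
}

#' Isotropic total variation of a slice
#'
#' `sum_i sqrt((D_i^H)^2 + (D_i^V)^2)` with forward finite differences and
#' replicate (zero-gradient) boundary on the last row/column. Zero exactly
#' when the image is constant.
#'
#' @param image numeric matrix or [slice_image()], finite values.
#' @return non-negative scalar.
#' @examples
#' tv_functional(matrix(1, 8, 8))  # 0
#' @export
tv_functional <- function(image) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) abort("tv_functional: image must be finite")
  g <- grad2(bare(image))
  sum(sqrt(g$h^2 + g$v^2))
}

#' Chambolle TV denoising
#'
#' Approximately minimises `0.5 * ||u - image||^2 + tau * TV(u)` by
#' Chambolle's dual projected-gradient iteration with dual step 1/8 (the
#' 2-D gradient/divergence operator-norm bound), run for a fixed number of
#' inner iterations with no inner tolerance. TV never increases and the
#' output approaches the input as `tau -> 0`.
#'
#' @param image numeric matrix or [slice_image()].
#' @param tau positive regularisation weight.
#' @param iters number of dual iterations (>= 1).
#' @return denoised matrix of the same shape (plain matrix).
#' @examples
#' noisy <- matrix(rnorm(64), 8, 8)
#' smooth <- tv_denoise(noisy, tau = 1, iters = 20)
#' @export
tv_denoise <- function(image, tau, iters = 40L) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) abort("tv_denoise: image must be finite")
  if (!is_scalar_num(tau) || tau <= 0)
    abort("tv_denoise: tau must be a positive scalar")
  stopifnot(is_scalar_num(iters), iters >= 1)
  g <- bare(image) / tau
  ph <- matrix(0, nrow(g), ncol(g))
  pv <- matrix(0, nrow(g), ncol(g))
  step <- 1 / 8
  for (it in seq_len(iters)) {
    u <- div2(ph, pv) - g
    gr <- grad2(u)
    denom <- 1 + step * sqrt(gr$h^2 + gr$v^2)
    ph <- (ph + step * gr$h) / denom
    pv <- (pv + step * gr$v) / denom
  }
  bare(image) - tau * div2(ph, pv)
}

#' TV-regularised reconstruction objective
#'
#' `0.5 * ||Y - R X||_2^2 + tau * TV(X)`: the penalised least-squares
#' objective whose minimiser is the TV-regularised reconstruction.
#'
#' @param image candidate slice (matrix or [slice_image()]).
#' @param sino measured [sinogram()] `Y`.
#' @param geom the [projection_geometry()] of `R`.
#' @param tau non-negative regularisation weight.
#' @return non-negative scalar.
#' @export
objective <- function(image, sino, geom, tau) {
  pred <- radon_forward(image, geom)$values
  0.5 * sum((sino$values - pred)^2) + tau * tv_functional(image)
}

# objective on the normalised operator, used inside the iteration
.obj_norm <- function(x_vec, y_vec, An, tau, side) {
  r <- y_vec - as.numeric(An %*% x_vec)
  0.5 * sum(r^2) + tau * tv_functional(matrix(x_vec, side, side))
}

# power-iteration estimate of the largest singular value of A
spectral_norm_est <- function(A, iters = 30L, seed = 1L) {
  v <- withr::with_seed(seed, rnorm(ncol(A)))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  sqrt(lam)
}

#' TV-regularised slice reconstruction by TwIST
#'
#' Minimises `0.5 * ||Y - R X||^2 + tau * TV(X)` with the two-step
#' iteration: `X_1 = G(X_0)`;
#' `X_{t+1} = (1 - alpha) X_{t-1} + (alpha - beta) X_t + beta G(X_t)`,
#' where `G(X) = Psi_tau(X + R^T (Y - R X))` and `Psi_tau` is the Chambolle
#' TV denoiser ([tv_denoise()]). The projector is divided by a
#' power-iteration estimate of its largest singular value before iterating,
#' and `tau` is dimensionless: the working regularisation weight is `tau`
#' times the data's intensity scale (the peak of the back-projected data on
#' the normalised operator), so a given `tau` exerts the same strength
#' whatever the recording scale of `Y` — scaling `Y` by `c` scales the
#' reconstruction by `c` at fixed `tau`. The returned image is on the
#' original intensity scale.
#'
#' A monotone safeguard rejects any step that increases the objective,
#' falling back to the plain one-step (IST) update, and stops if even that
#' increases it — so the objective trace is non-increasing in every run.
#'
#' @param sino measured [sinogram()].
#' @param geom a [projection_geometry()] (defaults to the sinogram's own).
#' @param params a [twist_params()].
#' @param out_side reconstructed side length; defaults to `n_detector`.
#' @return an object of class `reconstruction_result`: list with `image`
#'   ([slice_image()]), `objective_trace`, `iterations_run` and `params`.
#' @examples
#' geom <- projection_geometry(evenly_spaced_angles(24), n_detector = 24)
#' img <- matrix(0, 24, 24); img[8:16, 8:16] <- 1
#' res <- twist_reconstruct(radon_forward(img, geom), geom,
#'                          twist_params(tau = 0.01, tv_iters = 10,
#'                                       max_outer_iters = 20))
#' res$iterations_run
#' @export
twist_reconstruct <- function(sino, geom = sino$geometry,
                              params = twist_params(), out_side = NULL) {
  stopifnot(inherits(sino, "sinogram"), inherits(params, "twist_params"))
  side <- if (is.null(out_side)) geom$n_detector else as.integer(out_side)
  if (side > geom$n_detector)
    abort("twist_reconstruct: out_side exceeds n_detector")
  A <- radon_system_matrix(side, geom)
  s <- spectral_norm_est(A)
  An <- A / s
  y <- as.numeric(t(sino$values))
  # tau is dimensionless: the working regularisation weight is tau times the
  # data's intensity scale m (peak of the back-projected data on the
  # normalised operator), so the same tau grid acts identically on data
  # recorded at any intensity scale
  m <- max(abs(as.numeric(Matrix::crossprod(An, y))))
  if (m == 0) m <- 1
  tau <- params$tau * m

  gamma_op <- function(x_vec) {
    r <- y - as.numeric(An %*% x_vec)
    v <- x_vec + as.numeric(Matrix::crossprod(An, r))
    out <- as.numeric(tv_denoise(matrix(v, side, side), tau,
                                 params$tv_iters))
    if (params$nonneg) out[out < 0] <- 0
    out
  }

  x_prev <- switch(params$init_mode,
    zero = numeric(side * side),
    backproject = as.numeric(Matrix::crossprod(An, y)),
    fbp = {
      fp <- fbp_params(output_side = side)
      # FBP lives on the original intensity scale; lift to the normalised one
      s * as.numeric(bare(fbp_reconstruct(sino, fp)))
    })
  f_prev <- .obj_norm(x_prev, y, An, tau, side)
  trace <- f_prev

  x_cur <- gamma_op(x_prev)
  f_cur <- .obj_norm(x_cur, y, An, tau, side)
  if (!is.finite(f_cur))
    abort("twist_reconstruct: divergence (non-finite objective) at iteration 1")
  if (f_cur > f_prev) {            # safeguard on the very first step
    x_cur <- x_prev
    f_cur <- f_prev
  }
  trace <- c(trace, f_cur)
  iters <- 1L
  converged <- abs(f_prev - f_cur) / max(f_prev, .Machine$double.eps) <
    params$rel_tol

  alpha <- params$alpha
  beta <- params$beta
  while (!converged && iters < params$max_outer_iters) {
    g <- gamma_op(x_cur)
    x_new <- (1 - alpha) * x_prev + (alpha - beta) * x_cur + beta * g
    f_new <- .obj_norm(x_new, y, An, tau, side)
    if (!is.finite(f_new))
      abort("twist_reconstruct: divergence (non-finite objective) at iteration %d",
            iters + 1L)
    if (f_new > f_cur) {
      # monotone safeguard: fall back to the one-step (IST) update
      x_new <- g
      f_new <- .obj_norm(x_new, y, An, tau, side)
      if (!is.finite(f_new))
        abort("twist_reconstruct: divergence (non-finite objective) at iteration %d",
              iters + 1L)
      if (f_new > f_cur) break     # no descent available; stop at x_cur
    }
    x_prev <- x_cur
    f_prev <- f_cur
    x_cur <- x_new
    f_cur <- f_new
    trace <- c(trace, f_cur)
    iters <- iters + 1L
    denom <- max(f_prev, .Machine$double.eps)
    if (abs(f_prev - f_cur) / denom < params$rel_tol) break
  }

  structure(list(image = slice_image(matrix(x_cur / s, side, side),
                                     voxel_size = geom$detector_pitch),
                 objective_trace = trace,
                 iterations_run = iters,
                 params = params),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  tr <- x$objective_trace
  cat(sprintf("<reconstruction_result> %d x %d, %d iterations, objective %.6g -> %.6g\n",
              nrow(x$image), ncol(x$image), x$iterations_run,
              tr[1], tr[length(tr)]))
  invisible(x)
}

#' TV-regularised volume reconstruction by TwIST
#'
#' Applies [twist_reconstruct()] with one shared parameter set to every
#' slice of a projection stack; per-slice objective traces are returned as
#' an attribute.
#'
#' @param stack a [projection_stack()].
#' @param params a [twist_params()].
#' @param out_side reconstructed side length; defaults to `n_detector`.
#' @return a [volume_image()] (negative values clipped to zero) with
#'   attribute `objective_traces`, a list of per-slice traces.
#' @export
twist_volume <- function(stack, params = twist_params(), out_side = NULL) {
  stopifnot(inherits(stack, "projection_stack"))
  ns <- n_slices(stack)
  if (ns < 1) abort("twist_volume: empty stack")
  side <- if (is.null(out_side)) stack$geometry$n_detector
          else as.integer(out_side)
  out <- array(0, c(side, side, ns))
  traces <- vector("list", ns)
  for (k in seq_len(ns)) {
    res <- twist_reconstruct(get_sinogram(stack, k), stack$geometry,
                             params, out_side = side)
    out[, , k] <- bare(res$image)
    traces[[k]] <- res$objective_trace
  }
  out[out < 0] <- 0
  vol <- volume_image(out, voxel_size = stack$geometry$detector_pitch)
  attr(vol, "objective_traces") <- traces
  vol
}
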