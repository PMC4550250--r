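#' Volume and slice image containers
#'
#' A `volume_image` is a 3-D numeric array of non-negative finite values with
#' voxel-size metadata; axis 3 is the rotation (slice) axis, so `vol[, , k]`
#' is the k-th transaxial slice. A `slice_image` is the corresponding square
#' 2-D field. Both are thin S3 wrappers over plain arrays: all arithmetic and
#' subsetting of base arrays applies unchanged.
#'
#' @param values numeric array (3-D for volumes, 2-D square for slices).
#' @param voxel_size physical edge length of a voxel, micrometres.
#' @return an object of class `volume_image` or `slice_image`.
#' @examples
#' v <- volume_image(array(0, c(8, 8, 8)))
#' dim(v)
#' @export
volume_image <- function(values, voxel_size = 1) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("volume_image: `values` must be a 3-D array")
  if (!all(is.finite(values)))
    abort("volume_image: values must be finite")
  if (min(values) < 0)
    abort("volume_image: values must be non-negative")
  stopifnot(is_scalar_num(voxel_size), voxel_size > 0)
  structure(values, voxel_size = voxel_size,
            class = c("volume_image", class(values)))
}

#' @rdname volume_image
#' @export
slice_image <- function(values, voxel_size = 1) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    abort("slice_image: slice must be square (pad upstream)")
  if (!all(is.finite(values)))
    abort("slice_image: values must be finite")
  stopifnot(is_scalar_num(voxel_size), voxel_size > 0)
  structure(values, voxel_size = voxel_size,
            class = c("slice_image", class(values)))
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume_image> %d x %d x %d voxels (%.3g um/voxel), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], attr(x, "voxel_size"), min(x), max(x)))
  invisible(x)
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d pixels (%.3g um/voxel), range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "voxel_size"), min(x), max(x)))
  invisible(x)
}

# strip class/attrs down to a bare array/matrix
bare <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

voxel_size_of <- function(x) {
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) 1 else vs
}

#' Extract one transaxial slice of a volume
#'
#' @param vol a [volume_image()] (or plain 3-D array).
#' @param k slice index along the rotation axis (1-based).
#' @return a [slice_image()].
#' @export
get_slice <- function(vol, k) {
  d <- dim(vol)
  stopifnot(length(d) == 3L, k >= 1, k <= d[3])
  slice_image(bare(vol)[, , k, drop = TRUE], voxel_size = voxel_size_of(vol))
}
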