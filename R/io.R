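# normalised multi-page float TIFF with an affine-range sidecar: TIFF
# samples hold (x - min) / (max - min) in [0, 1] as 32-bit float, and
# <path>.range.json records min/max (plus any extra metadata) so reads
# invert the mapping exactly up to float32 quantisation
write_pages_scaled <- function(pages_array, path, meta = list()) {
  rng <- range(pages_array)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(pages_array)[3]), function(k)
    (pages_array[, , k, drop = TRUE] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(c(list(min = rng[1], max = rng[2]), meta),
                       paste0(path, ".range.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_pages_scaled <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  sidecar <- paste0(path, ".range.json")
  meta <- list(min = 0, max = 1)
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  scale <- meta$max - meta$min
  if (scale > 0) arr <- arr * scale + meta$min
  list(values = arr, meta = meta)
}

#' Write and read volumes as multi-page TIFF
#'
#' Volumes are stored as 32-bit float multi-page TIFF, one page per
#' transaxial slice (page k = `vol[, , k]`), normalised to `[0, 1]` with
#' the affine range recorded in a `<path>.range.json` sidecar (read back
#' exactly up to float32 quantisation). Without the sidecar, stored values
#' are returned as-is. `bits = 8` instead exports a windowed 0-255
#' contrast-scale version for figure use.
#'
#' @param vol a [volume_image()] (or 3-D array).
#' @param path output file path.
#' @param bits 32 (float + sidecar) or 8 (windowed, no sidecar).
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, bits = 32L) {
  vs <- voxel_size_of(vol)
  vol <- bare(vol)
  stopifnot(length(dim(vol)) == 3L, bits %in% c(8L, 32L))
  if (bits == 32L) {
    write_pages_scaled(vol, path, meta = list(voxel_size = vs))
  } else {
    rng <- range(vol)
    pages <- lapply(seq_len(dim(vol)[3]), function(k) {
      pg <- vol[, , k, drop = TRUE]
      if (diff(rng) > 0) (pg - rng[1]) / diff(rng) else pg * 0
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  }
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size voxel edge length to attach on read (micrometres);
#'   overrides any value recorded in the sidecar.
#' @export
read_volume_tiff <- function(path, voxel_size = NULL) {
  got <- read_pages_scaled(path)
  vs <- if (!is.null(voxel_size)) voxel_size
        else if (!is.null(got$meta$voxel_size)) got$meta$voxel_size else 1
  volume_image(got$values, voxel_size = vs)
}

#' Write and read projection stacks (acquisition layout)
#'
#' Stacks are written in acquisition layout — one TIFF page per rotation
#' angle, each page a camera frame `[slice (camera row), detector bin]` —
#' with a sidecar CSV angle manifest (`index`, `angle_deg`; 0-based
#' indices). `read_projection_stack` accepts the same layout and
#' reorganises it into per-slice sinograms.
#'
#' @param stack a [projection_stack()].
#' @param tiff_path output TIFF path.
#' @param manifest_path output CSV path; defaults next to the TIFF.
#' @return `tiff_path`, invisibly.
#' @export
write_projection_stack <- function(stack, tiff_path,
                                   manifest_path = sub("\\.tiff?$", "_angles.csv",
                                                       tiff_path)) {
  stopifnot(inherits(stack, "projection_stack"))
  v <- stack$values  # [angle, bin, slice] -> pages [slice, bin] per angle
  pages <- array(0, c(dim(v)[3], dim(v)[2], dim(v)[1]))
  for (a in seq_len(dim(v)[1])) pages[, , a] <- t(v[a, , , drop = TRUE])
  write_pages_scaled(pages, tiff_path,
                     meta = list(channel = stack$channel,
                                 noise_sd = stack$noise_sd,
                                 seed = stack$seed,
                                 detector_pitch = stack$geometry$detector_pitch))
  manifest <- data.frame(index = seq_len(dim(v)[1]) - 1L,
                         angle_deg = stack$geometry$angles_deg)
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(tiff_path)
}

#' @rdname write_projection_stack
#' @param detector_pitch physical bin pitch for the rebuilt geometry.
#' @param channel channel tag of the stored data.
#' @export
read_projection_stack <- function(tiff_path,
                                  manifest_path = sub("\\.tiff?$", "_angles.csv",
                                                      tiff_path),
                                  detector_pitch = NULL,
                                  channel = NULL) {
  got <- read_pages_scaled(tiff_path)
  pages <- got$values   # [slice, bin, angle]
  manifest <- read.csv(manifest_path)
  if (!all(c("index", "angle_deg") %in% names(manifest)))
    abort("read_projection_stack: manifest needs columns index, angle_deg")
  if (nrow(manifest) != dim(pages)[3])
    abort("read_projection_stack: manifest rows (%d) != TIFF pages (%d)",
          nrow(manifest), dim(pages)[3])
  ord <- order(manifest$index)
  manifest <- manifest[ord, ]
  pages <- pages[, , ord, drop = FALSE]
  if (is.null(detector_pitch))
    detector_pitch <- if (!is.null(got$meta$detector_pitch))
      got$meta$detector_pitch else 1
  if (is.null(channel))
    channel <- if (!is.null(got$meta$channel)) got$meta$channel
               else "fluorescence"
  d <- dim(pages)
  geom <- projection_geometry(manifest$angle_deg, n_detector = d[2],
                              detector_pitch = detector_pitch)
  v <- array(0, c(d[3], d[2], d[1]))
  for (a in seq_len(d[3])) v[a, , ] <- t(pages[, , a])
  noise_sd <- if (!is.null(got$meta$noise_sd)) got$meta$noise_sd else 0
  projection_stack(v, geom, channel = channel, noise_sd = noise_sd,
                   source = tiff_path)
}

#' Write and read a binary mask as 8-bit TIFF
#'
#' Masks are stored 0/255, one page per slice.
#'
#' @param mask logical 3-D array.
#' @param path file path.
#' @return `path` invisibly / logical array.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  pages <- lapply(seq_len(dim(mask)[3]),
                  function(k) mask[, , k, drop = TRUE] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  mask <- array(FALSE, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) mask[, , k] <- pages[[k]] > 0.5
  mask
}

#' Serialise / load a phantom specification as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `path` invisibly / a [phantom_spec()].
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  blobs <- lapply(raw$anatomy_blobs, function(b)
    list(center = as.numeric(b$center), semi_axes = as.numeric(b$semi_axes),
         intensity = as.numeric(b$intensity)))
  phantom_spec(shape = as.integer(raw$shape), voxel_size = raw$voxel_size,
               vessel_count = raw$vessel_count,
               radius_range = as.numeric(raw$radius_range),
               vessel_intensity = raw$vessel_intensity,
               intensity_range = if (is.null(raw$intensity_range)) c(1, 1)
                                 else as.numeric(raw$intensity_range),
               anatomy_blobs = blobs,
               background_intensity = raw$background_intensity,
               seed = raw$seed)
}
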