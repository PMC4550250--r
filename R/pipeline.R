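#' Experiment configuration for an angular down-sampling study
#'
#' Bundles everything one study needs: the phantom (or an input stack), the
#' dense angle count, the evenly spaced subset sizes to test, the TwIST
#' parameter grid, and the metric/segmentation settings. The dense FBP
#' reconstruction serves as the reference ("gold standard") image — note it
#' is itself a noisy reconstruction, not the ground-truth phantom.
#'
#' @param phantom a [phantom_spec()] (used unless `stacks` is supplied).
#' @param stacks optional named list with [projection_stack()] elements
#'   `fluorescence` and (optionally) `transmission`, replacing simulation.
#' @param dense_count number of angles of the dense acquisition.
#' @param subset_sizes integer vector of evenly spaced subset sizes, each
#'   at most `dense_count`.
#' @param tau_grid,tv_iters_grid TwIST parameter grid (non-empty).
#' @param noise_frac measurement read-noise standard deviation as a
#'   fraction of each channel's own noiseless projection peak (noise is a
#'   detector property, so it scales with the recorded dynamic range, not
#'   with voxel intensities).
#' @param fbp an [fbp_params()].
#' @param twist a [twist_params()] template (its `tau` / `tv_iters` are
#'   overridden by the grid during sweeps).
#' @param vessel a [vesselness_params()]; the default narrows the scale
#'   range to `[1, 4]` voxels, matched to the default study phantom's
#'   vessel radii (1.5-3 voxels).
#' @param ssim an [ssim_params()].
#' @param n_repeats random-subset repeats for uncertainty summaries (0
#'   disables them).
#' @param seed study seed (phantom noise, random subsets).
#' @param output_dir directory for [run_full_study()] artefacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(shape = c(64, 64, 16),
                                                     vessel_count = 24,
                                                     radius_range = c(1.5, 3),
                                                     intensity_range = c(0.4, 1)),
                              stacks = NULL,
                              dense_count = 160L,
                              subset_sizes = c(64L, 50L, 40L, 32L, 20L),
                              tau_grid = c(0.002, 0.006, 0.01),
                              tv_iters_grid = c(5L, 20L, 40L),
                              noise_frac = 0.02,
                              fbp = fbp_params(),
                              twist = twist_params(),
                              vessel = vesselness_params(sigma_max = 4,
                                                         n_scales = 4),
                              ssim = ssim_params(),
                              n_repeats = 0L,
                              seed = 1L,
                              output_dir = tempfile("optomo_study_")) {
  stopifnot(inherits(phantom, "phantom_spec") || !is.null(stacks),
            is_scalar_num(dense_count), dense_count >= 2,
            length(subset_sizes) >= 1, length(tau_grid) >= 1,
            length(tv_iters_grid) >= 1,
            is_scalar_num(noise_frac), noise_frac >= 0,
            inherits(fbp, "fbp_params"), inherits(twist, "twist_params"),
            inherits(vessel, "vesselness_params"), inherits(ssim, "ssim_params"),
            is_scalar_num(n_repeats), n_repeats >= 0, is_scalar_num(seed))
  subset_sizes <- sort(unique(as.integer(subset_sizes)), decreasing = TRUE)
  if (max(subset_sizes) > dense_count)
    abort("experiment_config: subset sizes must not exceed dense_count")
  structure(list(phantom = phantom, stacks = stacks,
                 dense_count = as.integer(dense_count),
                 subset_sizes = subset_sizes,
                 tau_grid = as.numeric(tau_grid),
                 tv_iters_grid = as.integer(tv_iters_grid),
                 noise_frac = noise_frac,
                 fbp = fbp, twist = twist, vessel = vessel, ssim = ssim,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

# simulate (or pass through) the dense two-channel stacks of a study;
# noise sd per channel = noise_frac * that channel's noiseless projection peak
study_stacks <- function(cfg) {
  if (!is.null(cfg$stacks)) return(cfg$stacks)
  fluor <- make_vessel_phantom(cfg$phantom)
  anat <- make_anatomy_phantom(cfg$phantom)
  side <- cfg$phantom$shape[1]
  geom <- projection_geometry(evenly_spaced_angles(cfg$dense_count),
                              n_detector = side,
                              detector_pitch = cfg$phantom$voxel_size)
  clean <- simulate_dataset(fluor, anat, geom, noise_sd = 0, seed = cfg$seed)
  sim <- simulate_dataset(fluor, anat, geom,
                          noise_sd = cfg$noise_frac *
                            c(max(clean$fluorescence$values),
                              max(clean$transmission$values)),
                          seed = cfg$seed)
  sim$phantoms <- list(fluorescence = fluor, anatomy = anat)
  sim
}

# override tau / tv_iters on a twist_params template
with_grid_cell <- function(tp, tau, tv_iters) {
  twist_params(tau = tau, tv_iters = tv_iters, alpha = tp$alpha,
               beta = tp$beta, max_outer_iters = tp$max_outer_iters,
               rel_tol = tp$rel_tol, init_mode = tp$init_mode,
               nonneg = tp$nonneg)
}

#' Sweep the TwIST parameter grid over angular subsets
#'
#' For every combination of evenly spaced subset size, `tau` and TV
#' iteration count, reconstructs the fluorescence channel with TwIST and
#' scores it by global SSIM against the dense FBP reference. Failures in
#' individual cells are recorded and the sweep continues. The per-subset
#' argmax cells identify the recommended settings; in sparse regimes the
#' optimum moves toward stronger regularisation (larger `tau`, more TV
#' iterations).
#'
#' @param cfg an [experiment_config()].
#' @param stacks optional precomputed result of the internal simulation
#'   (reused by [run_full_study()] to avoid recomputation).
#' @return list with `table` (one [metrics_record()] row per cell, plus an
#'   `error` column), `best` (argmax row per subset size) and `reference`
#'   (the dense FBP volume).
#' @export
run_parameter_sweep <- function(cfg, stacks = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(stacks)) stacks <- study_stacks(cfg)
  dense <- stacks$fluorescence
  reference <- fbp_volume(dense, cfg$fbp)
  rows <- NULL
  for (n_keep in cfg$subset_sizes) {
    idx <- downsample_angles(length(dense$geometry$angles_deg), n_keep)
    sub <- subset_angles(dense, idx)
    for (tau in cfg$tau_grid) {
      for (tvit in cfg$tv_iters_grid) {
        cell <- tryCatch({
          rec <- twist_volume(sub, with_grid_cell(cfg$twist, tau, tvit))
          s <- ssim_global(rec, reference, cfg$ssim)
          row <- metrics_record(n_keep, "twist", dense$channel, ssim = s,
                                tau = tau, tv_iters = tvit)
          row$error <- NA_character_
          row
        }, error = function(e) {
          row <- metrics_record(n_keep, "twist", dense$channel,
                                tau = tau, tv_iters = tvit)
          row$error <- conditionMessage(e)
          row
        })
        rows <- rbind(rows, cell)
      }
    }
  }
  ok <- !is.na(rows$ssim)
  best <- do.call(rbind, lapply(split(rows[ok, ], rows$n_projections[ok]),
                                function(d) d[which.max(d$ssim), ]))
  best <- best[order(best$n_projections, decreasing = TRUE), ]
  rownames(best) <- NULL
  list(table = rows, best = best, reference = reference)
}

#' Run the full down-sampling study end to end
#'
#' Simulates the two-channel acquisition, builds the dense FBP reference,
#' sweeps the TwIST grid on the fluorescence channel, reconstructs every
#' subset with both FBP and TwIST (at the per-subset optimal grid cell) in
#' both channels, segments the fluorescence reconstructions, scores SSIM
#' and Dice against the reference, optionally adds random-subset
#' uncertainty summaries, and writes all artefacts (float32 TIFF volumes,
#' masks, CSV tables, MIP renderings, config snapshot, JSON manifest) under
#' `cfg$output_dir`. Deterministic for fixed seeds.
#'
#' @param cfg an [experiment_config()].
#' @return invisibly, a list with `metrics` (full table), `sweep`, the
#'   reference volumes and the output manifest.
#' @export
run_full_study <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$output_dir, ...)
  manifest <- list(seed = cfg$seed, artefacts = character(), partial = character())
  add_art <- function(x) manifest$artefacts <<- c(manifest$artefacts, basename(x))

  stacks <- study_stacks(cfg)
  if (!is.null(cfg$phantom))
    write_phantom_spec(cfg$phantom, out("phantom_spec.yaml"))

  # dense FBP references, both channels
  ref_fluor <- fbp_volume(stacks$fluorescence, cfg$fbp)
  ref_trans <- fbp_volume(stacks$transmission, cfg$fbp)
  write_volume_tiff(ref_fluor, out("reference_fluorescence_fbp.tiff"))
  write_volume_tiff(ref_trans, out("reference_transmission_fbp.tiff"))
  add_art(out("reference_fluorescence_fbp.tiff"))
  add_art(out("reference_transmission_fbp.tiff"))

  ref_map <- vesselness_multiscale(ref_fluor, cfg$vessel)
  ref_mask <- segment_mask(ref_map, cfg$vessel)
  write_mask_tiff(ref_mask, out("reference_vessel_mask.tiff"))
  add_art(out("reference_vessel_mask.tiff"))

  sweep <- run_parameter_sweep(cfg, stacks = stacks)
  write.csv(sweep$table, out("sweep_table.csv"), row.names = FALSE)
  write.csv(sweep$best, out("sweep_best.csv"), row.names = FALSE)
  add_art(out("sweep_table.csv")); add_art(out("sweep_best.csv"))

  channels <- list(fluorescence = list(stack = stacks$fluorescence,
                                       ref = ref_fluor),
                   transmission = list(stack = stacks$transmission,
                                       ref = ref_trans))
  rows <- NULL
  for (n_keep in cfg$subset_sizes) {
    bi <- sweep$best[sweep$best$n_projections == n_keep, ]
    tp <- if (nrow(bi) == 1)
      with_grid_cell(cfg$twist, bi$tau, bi$tv_iters) else cfg$twist
    idx <- downsample_angles(cfg$dense_count, n_keep)
    for (ch in names(channels)) {
      sub <- subset_angles(channels[[ch]]$stack, idx)
      ref <- channels[[ch]]$ref
      for (method in c("fbp", "twist")) {
        tag <- sprintf("%s_%s_%03d", ch, method, n_keep)
        cell <- tryCatch({
          rec <- if (method == "fbp") fbp_volume(sub, cfg$fbp)
                 else twist_volume(sub, tp)
          write_volume_tiff(rec, out(paste0(tag, ".tiff")))
          add_art(out(paste0(tag, ".tiff")))
          s <- ssim_global(rec, ref, cfg$ssim)
          d <- NA_real_
          if (ch == "fluorescence") {
            m <- segment_mask(vesselness_multiscale(rec, cfg$vessel),
                              cfg$vessel)
            write_mask_tiff(m, out(paste0(tag, "_mask.tiff")))
            add_art(out(paste0(tag, "_mask.tiff")))
            d <- dice(m, ref_mask)
          }
          metrics_record(n_keep, method, sub$channel, ssim = s, dsi = d,
                         tau = if (method == "twist") tp$tau else NA_real_,
                         tv_iters = if (method == "twist") tp$tv_iters
                                    else NA_integer_)
        }, error = function(e) {
          manifest$partial <<- c(manifest$partial,
                                 paste(tag, conditionMessage(e)))
          NULL
        })
        rows <- rbind(rows, cell)
      }
    }
  }
  write.csv(rows, out("metrics.csv"), row.names = FALSE)
  add_art(out("metrics.csv"))

  # MIP rendering of the fluorescence reference
  mip <- mip_render(ref_fluor, axis = 3)
  write.csv(mip, out("reference_fluorescence_mip.csv"), row.names = FALSE)
  add_art(out("reference_fluorescence_mip.csv"))

  uncertainty <- NULL
  if (cfg$n_repeats >= 2) {
    for (n_keep in cfg$subset_sizes) {
      u <- subset_uncertainty(stacks$fluorescence, n_keep, cfg$n_repeats,
                              method = "twist", params = cfg$twist,
                              reference = ref_fluor, seed = cfg$seed,
                              ssim_p = cfg$ssim)
      u$summary$n_projections <- n_keep
      uncertainty <- rbind(uncertainty, u$summary)
    }
    write.csv(uncertainty, out("uncertainty.csv"), row.names = FALSE)
    add_art(out("uncertainty.csv"))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(metrics = rows, sweep = sweep,
                 reference = list(fluorescence = ref_fluor,
                                  transmission = ref_trans,
                                  vessel_mask = ref_mask),
                 uncertainty = uncertainty, manifest = manifest,
                 output_dir = cfg$output_dir))
}
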