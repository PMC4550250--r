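#' SSIM parameters
#'
#' Constants of the structural similarity index: `c1 = (k1 * L)^2` and
#' `c2 = (k2 * L)^2`, with `L` the dynamic range of the data. Defaults
#' `k1 = 0.01`, `k2 = 0.03`; when `dynamic_range` is `NULL` it is taken as
#' `max - min` over both images jointly.
#'
#' @param k1,k2 positive stabilisation factors.
#' @param dynamic_range positive dynamic range `L`, or `NULL` to infer.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  stopifnot(is_scalar_num(k1), k1 > 0, is_scalar_num(k2), k2 > 0)
  if (!is.null(dynamic_range))
    stopifnot(is_scalar_num(dynamic_range), dynamic_range > 0)
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range),
            class = "ssim_params")
}

#' Global structural similarity index
#'
#' Single-window SSIM over all voxels:
#' `(2 mu_X mu_G + c1) (2 cov_XG + c2) / ((mu_X^2 + mu_G^2 + c1) (var_X + var_G + c2))`
#' with means, (population) variances and covariance computed over the whole
#' field — one global window, not a sliding one. Symmetric in its arguments;
#' equals 1 exactly when `X == G`; values at or above 0.9 are conventionally
#' read as "highly similar".
#'
#' @param X,G volumes or slices of identical shape.
#' @param p an [ssim_params()].
#' @return scalar SSIM, at most 1.
#' @examples
#' a <- array(runif(64), c(4, 4, 4))
#' ssim_global(a, a)  # exactly 1
#' @export
ssim_global <- function(X, G, p = ssim_params()) {
  x <- as.numeric(X); g <- as.numeric(G)
  if (!identical(dim(X), dim(G)) || length(x) != length(g))
    abort("ssim_global: X and G must share one shape")
  L <- p$dynamic_range
  if (is.null(L)) {
    L <- max(x, g) - min(x, g)
    if (L <= 0)
      abort("ssim_global: degenerate dynamic range; supply dynamic_range explicitly")
  }
  c1 <- (p$k1 * L)^2
  c2 <- (p$k2 * L)^2
  n <- length(x)
  mx <- mean(x); mg <- mean(g)
  vx <- sum((x - mx)^2) / n
  vg <- sum((g - mg)^2) / n
  cxg <- sum((x - mx) * (g - mg)) / n
  ((2 * mx * mg + c1) * (2 * cxg + c2)) /
    ((mx^2 + mg^2 + c1) * (vx + vg + c2))
}

#' Dice similarity index of two binary masks
#'
#' Overlap measure `2 |A intersect B| / (|A| + |B|)` between binary
#' segmentations: 1 for perfect overlap, 0 for none. Two empty masks score
#' 1 by the 0/0 convention (reported via a message).
#'
#' @param Sx,Sg logical or 0/1 arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
#' dice(m, m)  # 1
#' @export
dice <- function(Sx, Sg) {
  if (!identical(dim(Sx), dim(Sg)))
    abort("dice: masks must share one shape")
  as_bin <- function(m, nm) {
    v <- as.numeric(m)
    if (!all(v %in% c(0, 1)))
      abort("dice: %s is not binary", nm)
    v > 0
  }
  a <- as_bin(Sx, "Sx"); b <- as_bin(Sg, "Sg")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) {
    message("dice: both masks empty; returning 1 (0/0 convention)")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Maximum intensity projection of a volume
#'
#' Renders the volume to 2-D by taking, along each axis-aligned viewing
#' ray, the maximum voxel value — the standard rendering for sparse bright
#' structures such as fluorescent vasculature.
#'
#' @param volume a [volume_image()] or 3-D array.
#' @param axis viewing axis (1, 2 or 3) collapsed by the projection.
#' @return numeric matrix over the remaining two axes.
#' @export
mip_render <- function(volume, axis = 3L) {
  vol <- bare(volume)
  if (length(dim(vol)) != 3L || length(vol) == 0L)
    abort("mip_render: need a non-empty 3-D volume")
  if (!axis %in% 1:3) abort("mip_render: axis must be 1, 2 or 3")
  apply(vol, setdiff(1:3, axis), max)
}

#' Label an SSIM or Dice value with its conventional interpretation
#' @param ssim,dsi metric values (either may be `NA`).
#' @return character labels (`"highly similar"`, `"excellent"`, ...).
#' @keywords internal
#' @noRd
quality_labels <- function(ssim = NA, dsi = NA) {
  lab_ssim <- if (is.na(ssim)) NA_character_
              else if (ssim >= 0.9) "highly similar" else "dissimilar"
  lab_dsi <- if (is.na(dsi)) NA_character_
             else if (dsi >= 0.7) "excellent"
             else if (dsi >= 0.6) "substantial" else "poor"
  c(ssim = lab_ssim, dsi = lab_dsi)
}

#' One row of a metrics table
#'
#' @param n_projections number of projections used.
#' @param method `"fbp"` or `"twist"`.
#' @param channel measurement channel.
#' @param ssim,dsi metric values (`NA` when not computed).
#' @param subset `"evenly-spaced"` or the random-subset seed used.
#' @param tau,tv_iters reconstruction parameters (`NA` for FBP).
#' @return one-row `data.frame`.
#' @export
metrics_record <- function(n_projections, method, channel,
                           ssim = NA_real_, dsi = NA_real_,
                           subset = "evenly-spaced",
                           tau = NA_real_, tv_iters = NA_integer_) {
  stopifnot(method %in% c("fbp", "twist"))
  if (!is.na(ssim) && ssim > 1 + 1e-12) abort("metrics_record: ssim exceeds 1")
  if (!is.na(dsi) && (dsi < 0 || dsi > 1)) abort("metrics_record: dsi outside [0, 1]")
  labs <- quality_labels(ssim, dsi)
  data.frame(n_projections = as.integer(n_projections), method = method,
             channel = channel, ssim = ssim, dsi = dsi,
             ssim_label = labs[["ssim"]], dsi_label = labs[["dsi"]],
             subset = as.character(subset), tau = tau,
             tv_iters = as.integer(tv_iters),
             stringsAsFactors = FALSE)
}

#' Sampling variability of sparse-view reconstruction quality
#'
#' Reconstructs the volume from `n_repeats` different random angular subsets
#' of `n_keep` projections, scores each against a reference volume, and
#' summarises each metric by its mean and maximum absolute deviation from
#' the mean (the error-bar convention for down-sampling studies).
#' Deterministic for a fixed seed.
#'
#' @param stack dense [projection_stack()].
#' @param n_keep number of projections per subset.
#' @param n_repeats number of random subsets (>= 2).
#' @param method `"fbp"` or `"twist"`.
#' @param params [fbp_params()] or [twist_params()] matching `method`.
#' @param reference reference [volume_image()] the scores are computed
#'   against.
#' @param seed integer seed; repeat `r` uses `seed + r - 1`.
#' @param ssim_p an [ssim_params()].
#' @param vessel_p optional [vesselness_params()]; when supplied, each
#'   reconstruction is also segmented and scored by Dice against the
#'   segmented reference.
#' @return list with `summary` (data.frame: metric, mean, max_abs_dev) and
#'   `records` (per-repeat metrics table).
#' @export
subset_uncertainty <- function(stack, n_keep, n_repeats, method = c("fbp", "twist"),
                               params = NULL, reference, seed = 1L,
                               ssim_p = ssim_params(), vessel_p = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "projection_stack"), n_repeats >= 2)
  n_total <- length(stack$geometry$angles_deg)
  if (n_keep > n_total)
    abort("subset_uncertainty: n_keep exceeds the available %d angles", n_total)
  if (is.null(params))
    params <- if (method == "fbp") fbp_params() else twist_params()
  ref_mask <- if (!is.null(vessel_p))
    segment_mask(vesselness_multiscale(reference, vessel_p), vessel_p) else NULL
  records <- NULL
  for (r in seq_len(n_repeats)) {
    sub_seed <- as.integer(seed) + r - 1L
    idx <- random_angle_subset(n_total, n_keep, seed = sub_seed)
    sub <- subset_angles(stack, idx)
    rec <- if (method == "fbp") fbp_volume(sub, params)
           else twist_volume(sub, params)
    s <- ssim_global(rec, reference, ssim_p)
    d <- NA_real_
    if (!is.null(vessel_p)) {
      m <- segment_mask(vesselness_multiscale(rec, vessel_p), vessel_p)
      d <- dice(m, ref_mask)
    }
    row <- metrics_record(n_keep, method, stack$channel, ssim = s, dsi = d,
                          subset = sub_seed,
                          tau = if (method == "twist") params$tau else NA_real_,
                          tv_iters = if (method == "twist") params$tv_iters
                                     else NA_integer_)
    records <- rbind(records, row)
  }
  summarise <- function(v) c(mean = mean(v), max_abs_dev = max(abs(v - mean(v))))
  metrics <- list(ssim = records$ssim)
  if (!is.null(vessel_p)) metrics$dsi <- records$dsi
  summ <- do.call(rbind, lapply(metrics, summarise))
  summary_df <- data.frame(metric = rownames(summ), mean = summ[, "mean"],
                           max_abs_dev = summ[, "max_abs_dev"],
                           row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary_df, records = records)
}

#' Quality-versus-projection-count plot
#'
#' SSIM (or Dice) against the number of projections, one line per
#' method/channel, with maximum-absolute-error bars when present.
#'
#' @param df metrics table with columns `n_projections`, `method`,
#'   `channel`, the metric column, and optionally `<metric>_err`.
#' @param metric `"ssim"` or `"dsi"`.
#' @return a ggplot object.
#' @export
plot_quality_curves <- function(df, metric = c("ssim", "dsi")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("plot_quality_curves requires ggplot2")
  df$group <- paste(df$method, df$channel, sep = " / ")
  df$value <- df[[metric]]
  err_col <- paste0(metric, "_err")
  df$err <- if (err_col %in% names(df)) df[[err_col]] else NA_real_
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = n_projections, y = value,
                                         colour = group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of projections", y = toupper(metric),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (any(!is.na(df$err))) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = value - err, ymax = value + err), width = 2)
  }
  gg
}
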