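# Volumetry, vessel segmentation, projections and the permeability index.

#' Volume of a voxel mask
#'
#' Sums the voxels set in the mask and multiplies by the voxel volume
#' (in-plane pixel area times slice thickness), i.e. the mask volume is the
#' pixel count per slice times the slice thickness. Additive over disjoint
#' masks.
#'
#' @param mask A [voxel_mask()].
#' @return Volume in mm^3.
#' @export
#' @examples
#' g <- geometry(c(4, 5, 5), 0.1, 0.5)
#' m <- array(FALSE, c(4, 5, 5)); m[1, 1:5, 1:5] <- TRUE
#' roi_volume(voxel_mask(m, g))  # 25 voxels * 0.1^2 * 0.5 = 0.125 mm^3
roi_volume <- function(mask) {
  stopifnot(inherits(mask, "bbb_mask"))
  sum(mask$mask) * voxel_volume(mask$geometry)
}

#' Segment blood vessels from a TOF stack
#'
#' Thresholds the time-of-flight angiography intensities inside the brain
#' ROI to keep only voxels representing flowing blood. The default adaptive
#' rule sets the threshold at mean + 3 SD of the within-ROI intensity;
#' passing a numeric `threshold` uses that absolute value instead. The
#' returned mask is always a subset of the ROI. A threshold above the stack
#' maximum yields an empty mask with a warning.
#'
#' @param tof An [image_stack()].
#' @param roi A [voxel_mask()] with matching geometry.
#' @param threshold `NULL` for the adaptive mean + `k_sd` * SD rule, or an
#'   absolute intensity.
#' @param k_sd Multiplier for the adaptive rule (default 3).
#' @return A [voxel_mask()] of vessel voxels.
#' @export
segment_vessels <- function(tof, roi, threshold = NULL, k_sd = 3) {
  stopifnot(inherits(tof, "bbb_image_stack"), inherits(roi, "bbb_mask"))
  check_same_geometry(tof$geometry, roi$geometry, "TOF stack and ROI")
  vals <- tof$intensities[roi$mask]
  if (!length(vals)) stopf("ROI is empty; nothing to segment")
  if (is.null(threshold)) {
    threshold <- mean(vals) + k_sd * stats::sd(vals)
  } else if (length(threshold) != 1L || !is.numeric(threshold) ||
             is.na(threshold)) {
    stopf("threshold must be NULL or a single number")
  }
  if (threshold > max(tof$intensities)) {
    warnf("vessel threshold %.4g exceeds the stack maximum %.4g; empty mask",
          threshold, max(tof$intensities))
  }
  mask <- roi$mask & (tof$intensities > threshold)
  voxel_mask(mask, tof$geometry)
}

#' Maximum intensity projection
#'
#' Per-pixel maximum of the stack along one axis, as used to visualize TOF
#' angiograms: the projection connects the high-intensity vessel voxels
#' across the collapsed dimension.
#'
#' @param tof An [image_stack()].
#' @param axis One of `"slice"`, `"row"`, `"col"`.
#' @return A 2-D numeric matrix.
#' @export
max_intensity_projection <- function(tof, axis = c("slice", "row", "col")) {
  stopifnot(inherits(tof, "bbb_image_stack"))
  axis <- match.arg(axis)
  d <- switch(axis, slice = 1L, row = 2L, col = 3L)
  apply(tof$intensities, setdiff(1:3, d), max)
}

#' BBB permeability index from baseline and post-contrast T1 maps
#'
#' Quantifies contrast leakage across the blood-brain barrier as
#' `delta_T1 / vessel_volume`, where `delta_T1` is the ROI-mean baseline T1
#' minus the ROI-mean post-contrast T1. When several post-contrast replicate
#' maps are supplied (the measurement is typically repeated), they are
#' averaged voxel-wise first; a voxel contributes only where the baseline
#' map and every replicate are valid, and both means are taken over those
#' jointly valid ROI voxels.
#'
#' @param baseline Baseline [t1_map()].
#' @param post_reps A single post-contrast [t1_map()] or a list of replicate
#'   maps.
#' @param roi Brain ROI [voxel_mask()].
#' @param vessels Vessel [voxel_mask()]; its volume must be positive.
#' @return An object of class `bbb_permeability_result` with
#'   `baseline_mean_t1`, `post_mean_t1`, `delta_t1` (seconds),
#'   `vessel_volume` (mm^3), `index` (s/mm^3) and `n_voxels` used.
#' @export
permeability_index <- function(baseline, post_reps, roi, vessels) {
  stopifnot(inherits(baseline, "bbb_t1_map"))
  if (inherits(post_reps, "bbb_t1_map")) post_reps <- list(post_reps)
  if (!length(post_reps)) stopf("at least one post-contrast map is required")
  for (m in post_reps) {
    stopifnot(inherits(m, "bbb_t1_map"))
    check_same_geometry(baseline$geometry, m$geometry,
                        "baseline and post-contrast maps")
  }
  stopifnot(inherits(roi, "bbb_mask"), inherits(vessels, "bbb_mask"))
  check_same_geometry(baseline$geometry, roi$geometry, "maps and ROI")
  check_same_geometry(baseline$geometry, vessels$geometry, "maps and vessels")

  vvol <- roi_volume(vessels)
  if (vvol <= 0) stopf("vessel volume is zero; the permeability index is undefined")

  post_valid <- Reduce(`&`, lapply(post_reps, `[[`, "valid"))
  post_t1 <- Reduce(`+`, lapply(post_reps, function(m) {
    x <- m$t1
    x[!m$valid] <- 0  # masked out below; avoid NA propagation in the sum
    x
  })) / length(post_reps)

  joint <- roi$mask & baseline$valid & post_valid
  n <- sum(joint)
  if (n == 0) stopf("no jointly valid voxels inside the ROI")

  base_mean <- mean(baseline$t1[joint])
  post_mean <- mean(post_t1[joint])
  delta <- base_mean - post_mean
  structure(
    list(baseline_mean_t1 = base_mean, post_mean_t1 = post_mean,
         delta_t1 = delta, vessel_volume = vvol, index = delta / vvol,
         n_voxels = n),
    class = "bbb_permeability_result"
  )
}

#' @export
print.bbb_permeability_result <- function(x, ...) {
  cat(sprintf(
    "<permeability> baseline T1 %.4g s, post T1 %.4g s, dT1 %.4g s\n  vessel volume %.4g mm^3, index %.4g s/mm^3 (%d voxels)\n",
    x$baseline_mean_t1, x$post_mean_t1, x$delta_t1, x$vessel_volume,
    x$index, x$n_voxels))
  invisible(x)
}
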