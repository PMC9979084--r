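#' Apply a two-point (or least-squares) density calibration
#'
#' Maps raw attenuation values to mg_HA/cm^3 through the straight line fitted
#' to calibration phantom pairs. With exactly two pairs this is the line
#' through the two points; with more, the ordinary least-squares fit.
#'
#' @param raw a [tomogram()] holding raw attenuation values.
#' @param pairs two-column matrix or data frame of `(raw_value, density)`
#'   calibration points; at least two with distinct raw values.
#' @return A calibrated [tomogram()] with the fitted `c(slope, intercept)`
#'   recorded in its `calibration` field.
#' @export
calibrate_density <- function(raw, pairs) {
  abort_if(!inherits(raw, "tomogram"), "`raw` must be a tomogram",
           class = "enamelmat_validation_error")
  pairs <- as.matrix(pairs)
  abort_if(ncol(pairs) != 2 || nrow(pairs) < 2,
           "`pairs` must have >= 2 rows of (raw, density)",
           class = "enamelmat_validation_error")
  x <- pairs[, 1]; y <- pairs[, 2]
  abort_if(diff(range(x)) == 0,
           "degenerate calibration pairs: all raw values equal",
           class = "enamelmat_calibration_error")
  fit <- stats::lm.fit(cbind(1, x), y)
  intercept <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  tomogram(raw$voxels * slope + intercept, raw$voxel_um,
           calibration = c(slope = unname(slope),
                           intercept = unname(intercept)))
}

#' Segment enamel by density window, closing and component filtering
#'
#' Classical reference segmentation standing in for a learned segmenter:
#' voxels with density in `[lo, hi]` are candidates, a binary closing (6-
#' connected, `closing_iter` passes) bridges sub-voxel gaps, and connected
#' components smaller than `min_component_voxels` are discarded. When two or
#' more components tie at or above the size threshold, all are kept (worn
#' enamel may be split).
#'
#' @param tom a calibrated, reoriented (or phantom-rendered) [tomogram()].
#' @param lo,hi density window bounds, mg_HA/cm^3 (`lo < hi`).
#' @param min_component_voxels smallest connected component retained.
#' @param closing_iter binary-closing passes (0 disables).
#' @return An [enamel_mask()].
#' @export
segment_enamel <- function(tom, lo, hi, min_component_voxels = 100L,
                           closing_iter = 1L) {
  abort_if(!inherits(tom, "tomogram"), "`tom` must be a tomogram",
           class = "enamelmat_validation_error")
  abort_if(!is_scalar_number(lo) || !is_scalar_number(hi) || lo >= hi,
           "`lo` must be less than `hi`",
           class = "enamelmat_validation_error")
  cand <- tom$voxels >= lo & tom$voxels <= hi
  abort_if(!any(cand),
           "empty segmentation: no voxels inside the density window",
           class = "enamelmat_empty_segmentation_error")
  if (closing_iter > 0) cand <- binary_closing(cand, closing_iter)
  lc <- label_components(cand)
  keep <- which(lc$sizes >= min_component_voxels)
  out <- array(lc$labels %in% keep & lc$labels > 0L, dim = dim(cand))
  abort_if(!any(out),
           "empty segmentation: all components below min_component_voxels",
           class = "enamelmat_empty_segmentation_error")
  enamel_mask(out, tom$voxel_um)
}

# principal axis of the mask's second-moment tensor; errors when the top two
# moments are indistinguishable (no preferred direction).
principal_axis <- function(mask_arr, ambiguity_tol = 0.95) {
  idx <- which(mask_arr)
  abort_if(length(idx) == 0, "mask is empty",
           class = "enamelmat_validation_error")
  co <- lin_to_coord(idx, dim(mask_arr))
  centroid <- colMeans(co)
  cv <- stats::cov(co)
  eg <- eigen(cv, symmetric = TRUE)
  abort_if(eg$values[2] / eg$values[1] > ambiguity_tol,
           "orientation ambiguous: mask has no dominant principal axis",
           class = "enamelmat_orientation_error")
  list(axis = eg$vectors[, 1], centroid = centroid, values = eg$values)
}

#' Reorient a tomogram so the tooth's long axis is vertical
#'
#' Finds the principal axis of the enamel mask's second-moment (inertia)
#' tensor, rotates the volume so this axis aligns with the slice (third
#' array) axis, and resamples: trilinear interpolation for density, nearest
#' neighbour for the mask. The axis sign is chosen so the cervical margin —
#' the lower-density end under the maturation ramp — lands at low slice
#' index; if the axial density difference is negligible, the end farther from
#' the centroid (the cusp) is pointed upward.
#'
#' @param tom a [tomogram()].
#' @param mask its [enamel_mask()] (non-empty).
#' @return A list with `tomogram`, `mask` (congruent, same dims as the
#'   input), `angle_deg` (tilt removed) and `axis` (the detected long-axis
#'   unit vector in input coordinates).
#' @export
reorient_long_axis <- function(tom, mask) {
  abort_if(!inherits(tom, "tomogram") || !inherits(mask, "enamel_mask"),
           "`tom`/`mask` must be tomogram and enamel_mask",
           class = "enamelmat_validation_error")
  check_congruent(tom, mask)
  pa <- principal_axis(mask$voxels)
  u <- pa$axis

  idx <- which(mask$voxels)
  co <- lin_to_coord(idx, dim(mask$voxels))
  proj <- as.numeric(sweep(co, 2, pa$centroid) %*% u)
  dens <- tom$voxels[idx]
  lo_end <- mean(dens[proj < 0]); hi_end <- mean(dens[proj >= 0])
  if (is.finite(lo_end) && is.finite(hi_end) &&
      abs(lo_end - hi_end) > 1e-6 * max(abs(lo_end), abs(hi_end), 1)) {
    if (lo_end > hi_end) u <- -u         # cervical (low density) points down
  } else {
    far <- which.max(abs(proj))
    if (proj[far] < 0) u <- -u           # far end (cusp) points up
  }

  rot <- rotation_between(u, c(0, 0, 1))
  angle <- acos(min(1, max(-1, abs(u[3])))) * 180 / pi
  dims <- dim(tom$voxels)
  vol_out <- resample_rotated(tom$voxels, rot, pa$centroid, dims,
                              method = "trilinear")
  mask_out <- resample_rotated(mask$voxels, rot, pa$centroid, dims,
                               method = "nearest")
  list(tomogram = tomogram(vol_out, tom$voxel_um,
                           calibration = tom$calibration),
       mask = enamel_mask(array(mask_out > 0, dims), mask$voxel_um),
       angle_deg = angle, axis = u)
}

#' Rotate a volume/mask pair by a known angle (test utility)
#'
#' Rigid rotation about one array axis through the volume centre, resampling
#' onto an output grid large enough to hold the rotated bounding box. Used to
#' build oracles for [reorient_long_axis()].
#'
#' @param tom a [tomogram()].
#' @param mask an [enamel_mask()] congruent with `tom`.
#' @param angle_deg rotation angle in degrees.
#' @param axis array axis (1, 2 or 3) about which to rotate.
#' @return A list with rotated `tomogram` and `mask`.
#' @export
rotate_volume <- function(tom, mask, angle_deg, axis = 1L) {
  check_congruent(tom, mask)
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  rot <- switch(as.character(axis),
    "1" = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    "2" = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    "3" = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3),
    abort_if(TRUE, "`axis` must be 1, 2 or 3",
             class = "enamelmat_validation_error"))
  dims <- dim(tom$voxels)
  centre <- (dims + 1) / 2
  corners <- as.matrix(expand.grid(c(1, dims[1]), c(1, dims[2]),
                                   c(1, dims[3])))
  rc <- sweep(corners, 2, centre) %*% t(rot)
  dims_out <- as.integer(ceiling(apply(rc, 2, max) - apply(rc, 2, min)) + 2L)
  vol_out <- resample_rotated(tom$voxels, rot, centre, dims_out,
                              method = "trilinear")
  mask_out <- resample_rotated(mask$voxels, rot, centre, dims_out,
                               method = "nearest")
  list(tomogram = tomogram(vol_out, tom$voxel_um,
                           calibration = tom$calibration),
       mask = enamel_mask(array(mask_out > 0, dims_out), mask$voxel_um))
}
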