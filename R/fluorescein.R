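#' Maximum intensity projection of a fluorescence stack
#'
#' Per-pixel maximum along one array axis — the standard way to collapse a
#' confocal z-stack of a cleaved enamel cross-section before assessing dye
#' penetration.
#'
#' @param s a `fluorescein_stack` (see [make_fluorescein_stack()]) or a
#'   plain 3D array.
#' @param axis array axis to project along (default 3, the slice axis).
#' @return A 2D matrix of intensities.
#' @export
max_intensity_projection <- function(s, axis = 3L) {
  v <- if (inherits(s, "fluorescein_stack")) s$voxels else s
  abort_if(!is.array(v) || length(dim(v)) != 3L,
           "`s` must be a 3D stack", class = "enamelmat_validation_error")
  abort_if(!axis %in% 1:3, "`axis` must be 1, 2 or 3",
           class = "enamelmat_validation_error")
  apply(v, setdiff(1:3, axis), max)
}

#' Fluorescein penetration-depth profile
#'
#' Bins a projection (or cross-section image) into depth bins of one pixel
#' moving inward from a straight surface line, and reports the mean
#' intensity per depth plus the depth at which intensity first falls below
#' `fraction` of the surface intensity. The surface intensity is normalised
#' as the mean of the first three bins, and the profile is monotone-smoothed
#' (running maximum from deep to shallow) before thresholding so isolated
#' speckle cannot terminate the search early. This turns a qualitative
#' penetration assessment into a defined, comparable metric.
#'
#' @param img 2D matrix; depth increases with row index.
#' @param surface_row row index of the surface line (default 1).
#' @param fraction threshold as a fraction of surface intensity, in (0, 1);
#'   default `1/e`, so for an exponential profile the reported depth is the
#'   decay constant.
#' @param voxel_um pixel pitch, micrometres.
#' @return A `penetration_profile`: data frame `depth_um`, `mean_intensity`
#'   with attributes `depth_at_fraction` (um; `NA` with `reached = FALSE`
#'   when the profile never falls below threshold), `fraction`,
#'   `surface_intensity`.
#' @export
penetration_depth <- function(img, surface_row = 1L, fraction = exp(-1),
                              voxel_um = 1) {
  abort_if(!is.matrix(img), "`img` must be a 2D matrix",
           class = "enamelmat_validation_error")
  abort_if(!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1,
           "`fraction` must be in (0, 1)",
           class = "enamelmat_validation_error")
  abort_if(surface_row < 1 || surface_row > nrow(img),
           "`surface_row` out of bounds",
           class = "enamelmat_validation_error")
  check_positive_scalar(voxel_um, "voxel_um")
  prof <- rowMeans(img[surface_row:nrow(img), , drop = FALSE])
  n <- length(prof)
  i0 <- mean(prof[seq_len(min(3L, n))])
  abort_if(!is.finite(i0) || i0 <= 0,
           "undefined surface: zero intensity in the surface bins",
           class = "enamelmat_undefined_surface_error")
  mono <- rev(cummax(rev(prof)))
  hit <- which(mono < fraction * i0)
  depth <- if (length(hit)) (hit[1] - 1L) * voxel_um else NA_real_
  structure(data.frame(depth_um = (seq_len(n) - 1L) * voxel_um,
                       mean_intensity = prof),
            depth_at_fraction = depth, reached = length(hit) > 0,
            fraction = fraction, surface_intensity = i0,
            class = c("penetration_profile", "data.frame"))
}

#' Fit the exponential decay constant of a penetration profile
#'
#' Log-linear least squares on the mean depth profile, restricted to depths
#' whose mean intensity exceeds `min_fraction` of the surface intensity
#' (deeper bins are dominated by the noise/detector floor and would bias the
#' slope). Accepts a stack (mean over all pixels per depth row — the highest
#' SNR estimate), a 2D image (row means), or a `penetration_profile`.
#'
#' @param x `fluorescein_stack`, 2D matrix, or `penetration_profile`.
#' @param surface_row surface line row (stack/image input).
#' @param min_fraction fit cut-off as a fraction of surface intensity.
#' @param voxel_um pixel pitch (stack input takes its own).
#' @return Fitted decay constant, micrometres.
#' @export
fit_depth_constant <- function(x, surface_row = 1L, min_fraction = 0.2,
                               voxel_um = 1) {
  if (inherits(x, "fluorescein_stack")) {
    voxel_um <- x$voxel_um
    surface_row <- x$surface_plane$row
    v <- x$voxels
    prof <- rowMeans(matrix(v, nrow = dim(v)[1]))[surface_row:dim(v)[1]]
    depth <- (seq_along(prof) - 1L) * voxel_um
  } else if (is.matrix(x)) {
    prof <- rowMeans(x[surface_row:nrow(x), , drop = FALSE])
    depth <- (seq_along(prof) - 1L) * voxel_um
  } else if (inherits(x, "penetration_profile")) {
    prof <- x$mean_intensity
    depth <- x$depth_um
  } else {
    abort_if(TRUE, "unsupported input to fit_depth_constant",
             class = "enamelmat_validation_error")
  }
  i0 <- mean(prof[seq_len(min(3L, length(prof)))])
  abort_if(!is.finite(i0) || i0 <= 0, "undefined surface intensity",
           class = "enamelmat_undefined_surface_error")
  keep <- prof > min_fraction * i0 & prof > 0
  abort_if(sum(keep) < 3, "too few bins above the fit cut-off",
           class = "enamelmat_validation_error")
  fit <- stats::lm.fit(cbind(1, depth[keep]), log(prof[keep]))
  slope <- fit$coefficients[2]
  abort_if(!is.finite(slope) || slope >= 0,
           "profile does not decay with depth",
           class = "enamelmat_validation_error")
  unname(-1 / slope)
}
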