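#' Calibrated micro-CT density volume
#'
#' A `tomogram` is the basic 3D container of the pipeline: an isotropic voxel
#' grid of mineral density in mg_HA/cm^3. The third array dimension is the
#' axial (slice) direction; after reorientation the tooth's long axis runs
#' along it with the cervical margin at low slice index. Physical position of
#' 0-based slice `i` is `(i + 0.5) * voxel_um`; axial distances in profiles
#' are reported in mm from the cervical-most enamel-containing slice.
#'
#' @param voxels numeric 3D array of densities (mg_HA/cm^3), or raw
#'   attenuation values if a calibration is to be applied later.
#' @param voxel_um isotropic voxel pitch in micrometres.
#' @param calibration optional named numeric vector `c(slope=, intercept=)`
#'   recording the raw-to-density map already applied.
#' @return An object of class `tomogram`.
#' @seealso [enamel_mask()], [calibrate_density()], [read_volume()]
#' @export
tomogram <- function(voxels, voxel_um, calibration = NULL) {
  abort_if(!is.array(voxels) || length(dim(voxels)) != 3L,
           "`voxels` must be a 3D array",
           class = "enamelmat_validation_error")
  abort_if(!all(is.finite(voxels)),
           "tomogram voxels must all be finite",
           class = "enamelmat_validation_error")
  check_positive_scalar(voxel_um, "voxel_um")
  if (!is.null(calibration)) {
    abort_if(!is.numeric(calibration) || length(calibration) != 2L ||
               calibration[["slope"]] <= 0,
             "`calibration` must be c(slope > 0, intercept)",
             class = "enamelmat_validation_error")
  }
  structure(list(voxels = voxels, voxel_um = as.numeric(voxel_um),
                 calibration = calibration),
            class = "tomogram")
}

#' Binary enamel label volume
#'
#' Congruent with its parent [tomogram()]: same array shape and voxel pitch,
#' `TRUE` where a voxel is enamel.
#'
#' @param voxels logical (or 0/1) 3D array.
#' @param voxel_um isotropic voxel pitch in micrometres.
#' @return An object of class `enamel_mask`.
#' @export
enamel_mask <- function(voxels, voxel_um) {
  abort_if(!is.array(voxels) || length(dim(voxels)) != 3L,
           "`voxels` must be a 3D array",
           class = "enamelmat_validation_error")
  if (!is.logical(voxels)) {
    abort_if(!all(voxels %in% c(0, 1)),
             "mask values must be 0/1 or logical",
             class = "enamelmat_validation_error")
    storage.mode(voxels) <- "logical"
  }
  check_positive_scalar(voxel_um, "voxel_um")
  structure(list(voxels = voxels, voxel_um = as.numeric(voxel_um)),
            class = "enamel_mask")
}

check_congruent <- function(tom, mask) {
  abort_if(!identical(dim(tom$voxels), dim(mask$voxels)),
           "tomogram and mask have different shapes",
           class = "enamelmat_validation_error")
  abort_if(abs(tom$voxel_um - mask$voxel_um) > 1e-9,
           "tomogram and mask have different voxel pitch",
           class = "enamelmat_validation_error")
  invisible(NULL)
}

#' @export
print.tomogram <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("tomogram: %d x %d x %d voxels at %.3g um\n", d[1], d[2], d[3],
              x$voxel_um))
  cat(sprintf("  density range: [%.1f, %.1f] mg_HA/cm^3\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.enamel_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("enamel_mask: %d x %d x %d voxels at %.3g um, %d foreground\n",
              d[1], d[2], d[3], x$voxel_um, sum(x$voxels)))
  invisible(x)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b `enamel_mask` objects (or logical arrays) of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  av <- if (inherits(a, "enamel_mask")) a$voxels else a
  bv <- if (inherits(b, "enamel_mask")) b$voxels else b
  abort_if(!identical(dim(av), dim(bv)), "masks have different shapes",
           class = "enamelmat_validation_error")
  sa <- sum(av); sb <- sum(bv)
  if (sa + sb == 0) return(1)
  2 * sum(av & bv) / (sa + sb)
}
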