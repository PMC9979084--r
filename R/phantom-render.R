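#' Rasterise a phantom into a tomogram and ground-truth mask
#'
#' Renders the axisymmetric phantom: a dentin core of radius
#' `dentin_radius_mm` (capped by enamel at the occlusal end), an enamel shell
#' whose thickness ramps from a thin cervical collar to
#' `enamel_thickness_mm` over `taper_frac` of the crown, with bulk enamel
#' voxels taking the density field at their axial position and voxels within
#' `surface_layer_um` of the outer surface taking the age-specific
#' surface-layer density. Gaussian noise of SD `noise_sd` is then added to the
#' whole volume. The render is deterministic under the spec's seed.
#'
#' The cervical collar is floored at two voxels so the enamel ring is complete
#' on every slice; this encloses the dentin core so that exterior-distance
#' operations (the 30 um surface shell) never see the dentin-enamel junction
#' as "surface".
#'
#' @param spec a [phantom_spec()].
#' @param field a `density_field` from [simulate_density_field()] built from
#'   the same spec.
#' @return A list with elements `tomogram` ([tomogram()]), `mask`
#'   (ground-truth [enamel_mask()]) and `labels` (integer array: 0 background,
#'   1 dentin, 2 enamel — a partition of the volume).
#' @export
render_tomogram <- function(spec, field) {
  abort_if(!inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec",
           class = "enamelmat_validation_error")
  abort_if(!inherits(field, "density_field"),
           "`field` must come from simulate_density_field()",
           class = "enamelmat_validation_error")
  age <- attr(field, "age_weeks")

  pitch <- spec$voxel_um / 1000          # mm per voxel
  r_out_max <- spec$dentin_radius_mm + spec$enamel_thickness_mm
  half <- ceiling(r_out_max / pitch) + 2L
  nx <- 2L * half
  nz <- max(1L, round(spec$crown_length_mm / pitch))
  abort_if(as.numeric(nx) * nx * nz > spec$max_voxels,
           sprintf("render of %d x %d x %d voxels exceeds max_voxels (%g)",
                   nx, nx, nz, spec$max_voxels),
           class = "enamelmat_size_error")

  cxy <- (seq_len(nx) - 0.5 - half) * pitch
  r <- sqrt(outer(cxy^2, cxy^2, `+`))    # nx x nx radial map

  z <- (seq_len(nz) - 0.5) * pitch       # slice centres, mm from cervix
  collar <- max(spec$taper_frac * spec$enamel_thickness_mm, 2 * pitch)
  thick <- pmax(collar,
                pmin(1, z / (spec$taper_frac * spec$crown_length_mm)) *
                  spec$enamel_thickness_mm)
  thick <- pmin(thick, spec$enamel_thickness_mm)
  r_outer <- spec$dentin_radius_mm + thick
  # enamel caps the dentin core at the occlusal end
  dentin_top_mm <- spec$crown_length_mm - spec$enamel_thickness_mm

  rho_axial <- interp_linear(field$x_mm, field$rho, z)
  rho_surface <- surface_rho_at_age(spec, age)
  surf_mm <- spec$surface_layer_um / 1000

  vol <- array(0, dim = c(nx, nx, nz))
  labels <- array(0L, dim = c(nx, nx, nz))
  for (k in seq_len(nz)) {
    has_dentin <- z[k] <= dentin_top_mm
    dent <- if (has_dentin) r <= spec$dentin_radius_mm else r < 0
    enam <- (r <= r_outer[k]) & !dent
    slab <- numeric(length(r))
    slab[dent] <- spec$dentin_rho
    surf <- enam & (r >= r_outer[k] - surf_mm)
    slab[enam] <- rho_axial[k]
    slab[surf] <- rho_surface
    vol[, , k] <- slab
    lab <- integer(length(r))
    lab[dent] <- 1L
    lab[enam] <- 2L
    labels[, , k] <- lab
  }
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(length(vol), 0, spec$noise_sd),
                                 dim = dim(vol)))
  }
  list(tomogram = tomogram(vol, spec$voxel_um),
       mask = enamel_mask(labels == 2L, spec$voxel_um),
       labels = labels)
}
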