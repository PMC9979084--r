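#' Synthetic tooth-phantom specification
#'
#' Parameterises the synthetic incisor used to exercise the pipeline: an
#' axisymmetric enamel shell over a dentin core, a mineral-density field that
#' rises linearly from the cervical margin to a mature plateau, a distinct
#' hypomineralised surface layer whose density depends on animal age, and
#' additive Gaussian imaging noise.
#'
#' The maturation kinematics are a travelling front: enamel is deposited at
#' the cervical margin while the tooth extends at `extension_rate_mm_per_wk`,
#' so in steady state the density at axial position `x` (mm from the cervical
#' margin) and age `t` satisfies `rho(x, t + dt) = rho(x + v*dt, t)` — the
#' space-for-time substitution on which the mineral-addition-rate statistic
#' rests. At `front_age_weeks` the foot of the linear maturation ramp sits
#' exactly at the cervical margin; at later ages the front has advanced by
#' `v * (age - front_age_weeks)` and the profile is correspondingly more
#' mature, reaching a constant plateau once the front has swept the crown.
#'
#' @param crown_length_mm crown height covered by the volume (mm).
#' @param enamel_thickness_mm maximum enamel shell thickness (mm).
#' @param dentin_radius_mm radius of the dentin core (mm).
#' @param voxel_um isotropic voxel pitch (micrometres). Default 6, the
#'   acquisition pitch this pipeline targets; renders for testing typically
#'   coarsen to 24-48.
#' @param extension_rate_mm_per_wk tooth extension speed `v` (mm/week).
#' @param gumline_mm distance of the gingival-emergence plane from the
#'   cervical margin (mm); supplied, not simulated.
#' @param rho_plateau mature-enamel plateau density, mg_HA/cm^3.
#' @param rho_initial bulk density of the newest enamel at the cervical
#'   margin, mg_HA/cm^3; must be below `rho_plateau`.
#' @param maturation_ramp_mm distance over which bulk density rises linearly
#'   from `rho_initial` to the plateau (mm).
#' @param surface_layer_um thickness of the distinct surface layer (um).
#' @param surface_rho_by_age named numeric vector mapping age in weeks to the
#'   surface-layer density; ages in between are linearly interpolated and
#'   clamped at the ends.
#' @param dentin_rho dentin core density, mg_HA/cm^3 (below the enamel
#'   plateau).
#' @param noise_sd SD of additive Gaussian imaging noise, mg_HA/cm^3.
#' @param front_age_weeks age (weeks) at which the ramp foot sits at the
#'   cervical margin; anchors the travelling front in time.
#' @param taper_frac fraction of the crown length over which the enamel
#'   shell thickens from its cervical collar to full thickness.
#' @param seed RNG seed; identical specs render bit-identical volumes.
#' @param max_voxels guard against accidental full-resolution renders; an
#'   error is raised if a render would exceed this many voxels.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(voxel_um = 48, noise_sd = 0)
#' field <- simulate_density_field(spec, age_weeks = 2)
#' head(field)
#' @export
phantom_spec <- function(crown_length_mm = 18,
                         enamel_thickness_mm = 0.3,
                         dentin_radius_mm = 0.8,
                         voxel_um = 6,
                         extension_rate_mm_per_wk = 2.5,
                         gumline_mm = 13,
                         rho_plateau = 2083,
                         rho_initial = 1870,
                         maturation_ramp_mm = 13,
                         surface_layer_um = 30,
                         surface_rho_by_age = c("2" = 1644, "4" = 1977,
                                                "16" = 1959),
                         dentin_rho = 1200,
                         noise_sd = 50,
                         front_age_weeks = 2,
                         taper_frac = 0.15,
                         seed = 1L,
                         max_voxels = 2e7) {
  for (nm in c("crown_length_mm", "enamel_thickness_mm", "dentin_radius_mm",
               "voxel_um", "extension_rate_mm_per_wk", "gumline_mm",
               "rho_plateau", "maturation_ramp_mm", "surface_layer_um",
               "dentin_rho", "max_voxels")) {
    check_positive_scalar(get(nm), nm)
  }
  abort_if(!is_scalar_number(rho_initial) || rho_initial <= 0,
           "`rho_initial` must be a positive number",
           class = "enamelmat_validation_error")
  abort_if(rho_initial >= rho_plateau,
           "`rho_initial` must be below `rho_plateau`",
           class = "enamelmat_validation_error")
  abort_if(voxel_um > enamel_thickness_mm * 1000,
           "`voxel_um` must not exceed the enamel thickness",
           class = "enamelmat_validation_error")
  abort_if(!is_scalar_number(noise_sd) || noise_sd < 0,
           "`noise_sd` must be a non-negative number",
           class = "enamelmat_validation_error")
  ages <- suppressWarnings(as.numeric(names(surface_rho_by_age)))
  abort_if(length(surface_rho_by_age) < 1 || anyNA(ages) ||
             any(!is.finite(surface_rho_by_age)),
           "`surface_rho_by_age` must be a named numeric vector (names = ages in weeks)",
           class = "enamelmat_validation_error")
  structure(list(
    crown_length_mm = crown_length_mm,
    enamel_thickness_mm = enamel_thickness_mm,
    dentin_radius_mm = dentin_radius_mm,
    voxel_um = voxel_um,
    extension_rate_mm_per_wk = extension_rate_mm_per_wk,
    gumline_mm = gumline_mm,
    rho_plateau = rho_plateau,
    rho_initial = rho_initial,
    maturation_ramp_mm = maturation_ramp_mm,
    surface_layer_um = surface_layer_um,
    surface_rho_by_age = surface_rho_by_age[order(ages)],
    dentin_rho = dentin_rho,
    noise_sd = noise_sd,
    front_age_weeks = front_age_weeks,
    taper_frac = taper_frac,
    seed = as.integer(seed),
    max_voxels = max_voxels
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: crown %.3g mm, shell %.3g mm over dentin r=%.3g mm, %g um voxels\n",
    x$crown_length_mm, x$enamel_thickness_mm, x$dentin_radius_mm, x$voxel_um))
  cat(sprintf("  bulk density %g -> %g over %.3g mm ramp; v = %.3g mm/wk\n",
              x$rho_initial, x$rho_plateau, x$maturation_ramp_mm,
              x$extension_rate_mm_per_wk))
  cat(sprintf("  surface layer %g um at rho(age) = {%s}; noise sd %g; seed %d\n",
              x$surface_layer_um,
              paste(sprintf("%s wk: %g", names(x$surface_rho_by_age),
                            x$surface_rho_by_age), collapse = ", "),
              x$noise_sd, x$seed))
  invisible(x)
}

#' Closed-form bulk mineral density of the phantom
#'
#' Evaluates the noise-free bulk (deep-enamel) density of the travelling-front
#' maturation model at axial positions `x_mm` and a given age. This is the
#' analytic ground truth against which rendered and profiled versions are
#' compared.
#'
#' @param spec a [phantom_spec()].
#' @param x_mm axial positions, mm from the cervical margin (vectorised).
#' @param age_weeks animal age in weeks (> 0; vectorised, recycled
#'   against `x_mm`).
#' @return Numeric vector of densities, mg_HA/cm^3.
#' @export
phantom_density <- function(spec, x_mm, age_weeks) {
  abort_if(!inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec",
           class = "enamelmat_validation_error")
  abort_if(!is.numeric(age_weeks) || length(age_weeks) < 1 ||
             any(!is.finite(age_weeks)) || any(age_weeks <= 0),
           "`age_weeks` must be positive",
           class = "enamelmat_validation_error")
  u <- x_mm + spec$extension_rate_mm_per_wk * (age_weeks - spec$front_age_weeks)
  slope <- (spec$rho_plateau - spec$rho_initial) / spec$maturation_ramp_mm
  pmin(spec$rho_plateau,
       spec$rho_initial + slope * pmax(u, 0))
}

# surface-layer density at a (possibly off-table) age, linear in age,
# clamped at the table ends
surface_rho_at_age <- function(spec, age_weeks) {
  ages <- as.numeric(names(spec$surface_rho_by_age))
  vals <- as.numeric(spec$surface_rho_by_age)
  if (length(ages) == 1L) return(vals)
  stats::approx(ages, vals, xout = age_weeks, rule = 2, ties = "ordered")$y
}

#' Sample the phantom's axial density field
#'
#' Returns the noise-free bulk density profile `rho(x)` of the phantom at one
#' age, sampled on a regular axial grid. The field is the analytic object the
#' renderer rasterises and the profiling stages should recover.
#'
#' @inheritParams phantom_density
#' @param axial_step_mm sampling pitch; defaults to the spec's voxel pitch.
#' @return A `density_field`: data frame with columns `x_mm`, `rho`, and
#'   attributes `age_weeks` and `axial_step_mm`. Sample points sit at voxel
#'   centres (`(i + 0.5) * step`).
#' @export
simulate_density_field <- function(spec, age_weeks,
                                   axial_step_mm = spec$voxel_um / 1000) {
  abort_if(!inherits(spec, "phantom_spec"), "`spec` must be a phantom_spec",
           class = "enamelmat_validation_error")
  abort_if(!is_scalar_number(age_weeks) || age_weeks <= 0,
           "`age_weeks` must be a single positive number",
           class = "enamelmat_validation_error")
  check_positive_scalar(axial_step_mm, "axial_step_mm")
  n <- max(1L, round(spec$crown_length_mm / axial_step_mm))
  x <- (seq_len(n) - 0.5) * axial_step_mm
  out <- data.frame(x_mm = x, rho = phantom_density(spec, x, age_weeks))
  attr(out, "age_weeks") <- age_weeks
  attr(out, "axial_step_mm") <- axial_step_mm
  class(out) <- c("density_field", "data.frame")
  out
}
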