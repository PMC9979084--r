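#' Design of a synthetic Vickers microhardness experiment
#'
#' Cell means for the age x gumline-location factorial emulated by
#' [make_hardness_table()]. Defaults follow the hardness structure of
#' developing pig incisors: the softest enamel is pre-eruptive in the
#' youngest animals (224 HV at 2 weeks below the gumline), post-eruptive
#' enamel of the same animals is markedly harder (344 HV), and hardness
#' saturates in older animals (up to 372 HV).
#'
#' @param cell_means numeric matrix of HV cell means; rows = ages (weeks),
#'   columns = locations `below`, `at`, `above` the gumline; dimnames
#'   required.
#' @param residual_sd within-cell SD of HV.
#' @param replicates_per_cell animals per age (each contributes one value per
#'   location); must be >= 2.
#' @param indents_per_site indent replicates per animal x location site (the
#'   protocol uses nine indents per site).
#' @param seed RNG seed.
#' @return An object of class `hardness_design`.
#' @export
hardness_design <- function(cell_means = NULL, residual_sd = 50,
                            replicates_per_cell = 3L, indents_per_site = 1L,
                            seed = 1L) {
  if (is.null(cell_means)) {
    cell_means <- matrix(c(224, 290, 344,
                           330, 350, 372,
                           340, 350, 355),
                         nrow = 3, byrow = TRUE,
                         dimnames = list(c("2", "4", "16"),
                                         c("below", "at", "above")))
  }
  abort_if(!is.matrix(cell_means) || is.null(dimnames(cell_means)),
           "`cell_means` must be a matrix with age and location dimnames",
           class = "enamelmat_validation_error")
  abort_if(any(cell_means <= 0), "all cell means must be positive",
           class = "enamelmat_validation_error")
  abort_if(!is_scalar_number(residual_sd) || residual_sd < 0,
           "`residual_sd` must be non-negative",
           class = "enamelmat_validation_error")
  abort_if(replicates_per_cell < 2,
           "`replicates_per_cell` must be at least 2",
           class = "enamelmat_validation_error")
  structure(list(cell_means = cell_means, residual_sd = residual_sd,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 indents_per_site = as.integer(indents_per_site),
                 seed = as.integer(seed)),
            class = "hardness_design")
}

#' Generate a synthetic Vickers hardness table
#'
#' Draws a balanced long-format table of indent values
#' `HV = cell mean + N(0, residual_sd)` with `age_weeks` and `level`
#' (gumline location) factors, one animal id per replicate within age, and
#' `region`/`side` bookkeeping columns matching the CSV dialect
#' (`animal_id,age_weeks,level,region,side,hv`). Deterministic under the
#' design's seed.
#'
#' @param design a [hardness_design()].
#' @return A `data.frame` with columns `animal_id`, `age_weeks`, `level`,
#'   `region`, `side`, `hv`.
#' @export
make_hardness_table <- function(design) {
  abort_if(!inherits(design, "hardness_design"),
           "`design` must be a hardness_design",
           class = "enamelmat_validation_error")
  ages <- rownames(design$cell_means)
  levels_ <- colnames(design$cell_means)
  grid <- expand.grid(rep = seq_len(design$replicates_per_cell),
                      indent = seq_len(design$indents_per_site),
                      level = levels_, age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- design$cell_means[cbind(grid$age, grid$level)]
  hv <- with_seed(design$seed,
                  mu + stats::rnorm(nrow(grid), 0, design$residual_sd))
  sides <- c("buccal", "lingual")
  data.frame(
    animal_id = sprintf("pig_%s_%02d", grid$age, grid$rep),
    age_weeks = as.numeric(grid$age),
    level = factor(grid$level, levels = c("below", "at", "above")),
    region = "mid",
    side = sides[(grid$indent - 1L) %% 2L + 1L],
    hv = hv,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic fluorescein confocal stack
#'
#' Produces a 3D intensity stack whose noise-free mean decays exponentially
#' with distance from a flat crown-surface plane:
#' `I(d) = surface_intensity * exp(-d / depth_constant_um)`. Gaussian noise
#' is added and the result clipped at zero (detector floor), matching the
#' non-negativity of fluorescence intensities.
#'
#' @param depth_constant_um 1/e penetration depth of the dye (um); smaller
#'   values emulate enamel that has sealed with time in the mouth.
#' @param surface_intensity mean intensity at the surface (arbitrary units).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @param dim integer vector `c(rows, cols, slices)`; depth runs along rows.
#' @param voxel_um isotropic pixel pitch (um).
#' @param surface_row row index of the crown surface plane.
#' @return A `fluorescein_stack`: list with `voxels`, `voxel_um`,
#'   `surface_plane = list(row, axis)`.
#' @export
make_fluorescein_stack <- function(depth_constant_um, surface_intensity = 1000,
                                   noise_sd = 0, seed = 1L,
                                   dim = c(96L, 64L, 16L), voxel_um = 2,
                                   surface_row = 1L) {
  check_positive_scalar(depth_constant_um, "depth_constant_um")
  check_positive_scalar(surface_intensity, "surface_intensity")
  check_positive_scalar(voxel_um, "voxel_um")
  abort_if(!is_scalar_number(noise_sd) || noise_sd < 0,
           "`noise_sd` must be non-negative",
           class = "enamelmat_validation_error")
  abort_if(surface_row < 1 || surface_row > dim[1],
           "`surface_row` out of bounds",
           class = "enamelmat_validation_error")
  d_um <- pmax(0, (seq_len(dim[1]) - surface_row)) * voxel_um
  mean_row <- surface_intensity * exp(-d_um / depth_constant_um)
  mean_row[seq_len(dim[1]) < surface_row] <- 0
  vox <- array(rep(mean_row, times = dim[2] * dim[3]), dim = dim)
  if (noise_sd > 0) {
    vox <- vox + with_seed(seed, array(stats::rnorm(length(vox), 0, noise_sd),
                                       dim = dim))
    vox[vox < 0] <- 0
  }
  structure(list(voxels = vox, voxel_um = voxel_um,
                 surface_plane = list(row = as.integer(surface_row),
                                      axis = 1L)),
            class = "fluorescein_stack")
}
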