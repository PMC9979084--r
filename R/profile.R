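#' Outer surface shell of an enamel mask
#'
#' Extracts the enamel voxels lying within `depth_um` (Euclidean,
#' voxel-centre metric scaled by the pitch) of the *exterior* background —
#' the non-enamel component reachable from the volume corners. Interior
#' cavities such as the dentin core therefore never contribute "surface"
#' voxels, so the dentin-enamel junction is excluded by construction.
#'
#' @param mask a non-empty [enamel_mask()].
#' @param depth_um shell depth in micrometres (default 30, the outer enamel
#'   layer analysed in developing teeth).
#' @return A `surface_shell_mask`: an [enamel_mask()] subclass with a
#'   `depth_um` field. A warning is raised when `depth_um < voxel_um / 2`
#'   (the shell may be empty at that pitch).
#' @export
surface_shell <- function(mask, depth_um = 30) {
  abort_if(!inherits(mask, "enamel_mask"), "`mask` must be an enamel_mask",
           class = "enamelmat_validation_error")
  abort_if(!any(mask$voxels), "mask is empty",
           class = "enamelmat_validation_error")
  check_positive_scalar(depth_um, "depth_um")
  if (depth_um < mask$voxel_um / 2) {
    warning("depth_um is below half the voxel pitch; shell may be empty")
  }
  m <- mask$voxels
  d <- dim(m)
  ext <- exterior_background(m)
  # offsets beyond the volume diameter can never connect two voxels
  r_vox <- min(floor(depth_um / mask$voxel_um), max(d))
  shell <- array(FALSE, d)
  if (r_vox >= 0) {
    offs <- as.matrix(expand.grid(-r_vox:r_vox, -r_vox:r_vox, -r_vox:r_vox))
    offs <- offs[sqrt(rowSums(offs^2)) * mask$voxel_um <= depth_um, ,
                 drop = FALSE]
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      if (all(o == 0)) next
      # target region of m overlapping ext shifted by o
      t1 <- pmax(1, 1 - o); t2 <- pmin(d, d - o)
      if (any(t2 < t1)) next
      s1 <- t1 + o; s2 <- t2 + o
      sub <- m[t1[1]:t2[1], t1[2]:t2[2], t1[3]:t2[3], drop = FALSE] &
        ext[s1[1]:s2[1], s1[2]:s2[2], s1[3]:s2[3], drop = FALSE]
      cur <- shell[t1[1]:t2[1], t1[2]:t2[2], t1[3]:t2[3], drop = FALSE]
      shell[t1[1]:t2[1], t1[2]:t2[2], t1[3]:t2[3]] <- cur | sub
    }
  }
  out <- enamel_mask(shell, mask$voxel_um)
  out$depth_um <- depth_um
  class(out) <- c("surface_shell_mask", class(out))
  out
}

new_axial_profile <- function(df, voxel_um, gumline_mm, smoothed = FALSE,
                              window = NA_integer_) {
  structure(df,
            voxel_um = voxel_um, gumline_mm = gumline_mm,
            smoothed = smoothed, window = window,
            class = c("axial_profile", "data.frame"))
}

#' Axial (per-slice) mineral-density profile
#'
#' For every axial slice, the mean density over mask voxels and the enamel
#' cross-sectional area `voxels * (voxel_um/1000)^2`. Slices whose area falls
#' below `min_area_mm2` are dropped (absent, not zero-filled): near the
#' cervical margin the enamel cross-section approaches the voxel size, where
#' partial-volume and segmentation errors would otherwise dominate. Axial
#' position is measured in mm from the cervical-most enamel-containing slice
#' (before filtering), with the cervical margin at low slice index.
#'
#' @param tom a reoriented [tomogram()].
#' @param mask its congruent [enamel_mask()].
#' @param min_area_mm2 area filter threshold (default 0.02 mm^2).
#' @param gumline_mm axial position of the gingival-emergence plane, mm from
#'   the cervical margin; a supplied landmark, required for band reporting.
#' @return An `axial_profile`: data frame `x_mm`, `mean_density`, `area_mm2`
#'   with attributes `gumline_mm`, `voxel_um`, `smoothed`, `window`.
#' @export
axial_profile <- function(tom, mask, min_area_mm2 = 0.02, gumline_mm) {
  abort_if(!inherits(tom, "tomogram") || !inherits(mask, "enamel_mask"),
           "`tom`/`mask` must be tomogram and enamel_mask",
           class = "enamelmat_validation_error")
  check_congruent(tom, mask)
  abort_if(!is_scalar_number(min_area_mm2) || min_area_mm2 < 0,
           "`min_area_mm2` must be a non-negative number",
           class = "enamelmat_validation_error")
  abort_if(missing(gumline_mm) || !is_scalar_number(gumline_mm),
           "`gumline_mm` is a required landmark (mm from cervical margin)",
           class = "enamelmat_validation_error")
  d <- dim(tom$voxels)
  nz <- d[3]
  vm <- matrix(tom$voxels, ncol = nz)
  mm <- matrix(mask$voxels, ncol = nz)
  counts <- colSums(mm)
  sums <- colSums(vm * mm)
  pitch_mm <- tom$voxel_um / 1000
  area <- counts * pitch_mm^2
  k0 <- which(counts > 0)[1]
  abort_if(is.na(k0), "mask is empty", class = "enamelmat_empty_profile_error")
  keep <- counts > 0 & area >= min_area_mm2
  abort_if(!any(keep), "no slices survive the area filter",
           class = "enamelmat_empty_profile_error")
  df <- data.frame(x_mm = (which(keep) - k0) * pitch_mm,
                   mean_density = sums[keep] / counts[keep],
                   area_mm2 = area[keep])
  new_axial_profile(df, tom$voxel_um, gumline_mm)
}

#' Moving-average smoothing of an axial profile
#'
#' Centred moving average of `mean_density` over `window` samples (default
#' 5). Edges use shrinking symmetric windows (widths 1, 3, ..., `window`), so
#' profile length is preserved and no edge bias is introduced; `x_mm` and
#' `area_mm2` are unchanged.
#'
#' @param p an `axial_profile`.
#' @param window odd window width in samples.
#' @return The smoothed `axial_profile` with its `smoothed`/`window`
#'   attributes set.
#' @export
smooth_profile <- function(p, window = 5L) {
  abort_if(!inherits(p, "axial_profile"), "`p` must be an axial_profile",
           class = "enamelmat_validation_error")
  abort_if(window %% 2 == 0 || window < 1,
           "`window` must be odd and >= 1",
           class = "enamelmat_validation_error")
  n <- nrow(p)
  abort_if(window > n, "`window` exceeds profile length",
           class = "enamelmat_validation_error")
  half <- (window - 1L) %/% 2L
  y <- p$mean_density
  sm <- vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(y[(i - h):(i + h)])
  }, numeric(1))
  out <- p
  out$mean_density <- sm
  attr(out, "smoothed") <- TRUE
  attr(out, "window") <- as.integer(window)
  out
}

#' Mean and SD of density over an axial band relative to the gumline
#'
#' Averages `mean_density` over slices whose position relative to the
#' registered gumline lies in the half-open band `[from_mm, to_mm)`, so that
#' adjacent bands partition the axis. The band `(0, 3)` mm above the gumline
#' is the standard reporting band for erupted surface enamel.
#'
#' @param p an `axial_profile` (carries `gumline_mm`).
#' @param from_mm,to_mm band limits, mm relative to the gumline
#'   (`from_mm < to_mm`).
#' @return Named numeric vector `c(mean, sd, n)`.
#' @export
band_mean <- function(p, from_mm = 0, to_mm = 3) {
  abort_if(!inherits(p, "axial_profile"), "`p` must be an axial_profile",
           class = "enamelmat_validation_error")
  abort_if(from_mm >= to_mm, "`from_mm` must be below `to_mm`",
           class = "enamelmat_validation_error")
  rel <- p$x_mm - attr(p, "gumline_mm")
  sel <- rel >= from_mm & rel < to_mm
  abort_if(!any(sel), "band contains no profile samples",
           class = "enamelmat_empty_band_error")
  v <- p$mean_density[sel]
  c(mean = mean(v), sd = stats::sd(v), n = sum(sel))
}

#' Pointwise average of several axial profiles
#'
#' Aligns profiles at the cervical margin (`x = 0`), restricts to the axial
#' range shared by all, interpolates each linearly onto the first profile's
#' grid, and reports the pointwise mean and sample SD — the n-samples-per-age
#' summary used when several teeth are profiled.
#'
#' @param ps list of >= 2 `axial_profile` objects.
#' @return An `axial_profile` with columns `x_mm`, `mean_density`, `sd`, `n`.
#' @export
average_profiles <- function(ps) {
  abort_if(!is.list(ps) || length(ps) < 2 ||
             !all(vapply(ps, inherits, logical(1), "axial_profile")),
           "`ps` must be a list of >= 2 axial_profile objects",
           class = "enamelmat_validation_error")
  lo <- max(vapply(ps, function(p) min(p$x_mm), numeric(1)))
  hi <- min(vapply(ps, function(p) max(p$x_mm), numeric(1)))
  abort_if(lo > hi, "profiles have disjoint x ranges",
           class = "enamelmat_alignment_error")
  grid <- ps[[1]]$x_mm[ps[[1]]$x_mm >= lo & ps[[1]]$x_mm <= hi]
  abort_if(length(grid) == 0, "no shared grid points",
           class = "enamelmat_alignment_error")
  ys <- vapply(ps, function(p) interp_linear(p$x_mm, p$mean_density, grid),
               numeric(length(grid)))
  ys <- matrix(ys, nrow = length(grid))
  df <- data.frame(x_mm = grid,
                   mean_density = rowMeans(ys),
                   sd = apply(ys, 1, stats::sd),
                   n = length(ps))
  new_axial_profile(df, attr(ps[[1]], "voxel_um"),
                    attr(ps[[1]], "gumline_mm"),
                    smoothed = attr(ps[[1]], "smoothed"),
                    window = attr(ps[[1]], "window"))
}
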