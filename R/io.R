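#' Write a volume to NIfTI or multi-page TIFF
#'
#' NIfTI (`.nii` / `.nii.gz`) stores 32-bit float densities with the voxel
#' pitch in the header and round-trips losslessly through [read_volume()].
#' TIFF stacks are written as 32-bit float pages; because the TIFF writer
#' works on the \[0, 1\] range, densities are divided by `scale` on write
#' (and multiplied back on read), and TIFF carries no pitch, so `voxel_um`
#' must be re-supplied when reading. Masks are written as 8-bit (TIFF) or
#' uint8 (NIfTI) 0/1 volumes.
#'
#' @param x a [tomogram()] or [enamel_mask()].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.tif`, `.tiff`).
#' @param scale TIFF intensity scale (mg_HA/cm^3 mapping to 1.0); default
#'   4000 leaves headroom above fully mineralised enamel.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, scale = 4000) {
  is_mask <- inherits(x, "enamel_mask")
  abort_if(!is_mask && !inherits(x, "tomogram"),
           "`x` must be a tomogram or enamel_mask",
           class = "enamelmat_validation_error")
  ext <- volume_ext(path)
  if (ext %in% c("nii", "nii.gz")) {
    p_mm <- x$voxel_um / 1000
    arr <- if (is_mask) array(as.integer(x$voxels), dim(x$voxels)) else x$voxels
    img <- RNifti::asNifti(arr,
                           list(pixdim = c(3, p_mm, p_mm, p_mm, 0, 0, 0, 0)),
                           datatype = if (is_mask) "uint8" else "float")
    RNifti::writeNifti(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    d <- dim(x$voxels)
    if (is_mask) {
      pages <- lapply(seq_len(d[3]), function(k) {
        matrix(as.numeric(x$voxels[, , k]), d[1], d[2])
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 8)
    } else {
      abort_if(any(x$voxels < 0) || any(x$voxels > scale),
               "densities outside [0, scale]: raise `scale` for TIFF output",
               class = "enamelmat_format_error")
      pages <- lapply(seq_len(d[3]), function(k) {
        matrix(x$voxels[, , k] / scale, d[1], d[2])
      })
      tiff::writeTIFF(pages, path, bits.per.sample = 32)
    }
  } else {
    abort_if(TRUE, sprintf("unknown volume format: %s", ext),
             class = "enamelmat_format_error")
  }
  invisible(path)
}

#' Read a volume from NIfTI or multi-page TIFF
#'
#' @param path input path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param voxel_um isotropic pitch in micrometres; required for TIFF,
#'   optional override for NIfTI.
#' @param mask logical: return an [enamel_mask()] (non-zero voxels) instead
#'   of a [tomogram()].
#' @param scale TIFF intensity scale used at write time.
#' @return A [tomogram()] or [enamel_mask()].
#' @export
read_volume <- function(path, voxel_um = NULL, mask = FALSE, scale = 4000) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path),
           class = "enamelmat_format_error")
  ext <- volume_ext(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (is.null(voxel_um)) {
      abort_if(max(pd) - min(pd) > 1e-6 * max(pd),
               "anisotropic voxels: resample or pass `voxel_um` explicitly",
               class = "enamelmat_format_error")
      voxel_um <- pd[1] * 1000
    }
    arr <- array(as.numeric(img), dim = dim(img))
  } else if (ext %in% c("tif", "tiff")) {
    abort_if(is.null(voxel_um),
             "TIFF carries no voxel pitch: `voxel_um` is required",
             class = "enamelmat_format_error")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (!mask) arr <- arr * scale
  } else {
    abort_if(TRUE, sprintf("unknown volume format: %s", ext),
             class = "enamelmat_format_error")
  }
  if (mask) enamel_mask(arr != 0, voxel_um) else tomogram(arr, voxel_um)
}

volume_ext <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

header_comments <- function(fields) {
  vapply(names(fields), function(nm) sprintf("# %s=%s", nm,
                                             format(fields[[nm]])),
         character(1))
}

#' Write an axial profile (or rate profile) to CSV
#'
#' Columns `x_mm,mean_density,area_mm2[,sd]` (profiles) or `x_mm,rate[,sd]`
#' (rate profiles), preceded by `#` comment lines recording the gumline,
#' smoothing, mode and delta-x metadata plus provenance.
#'
#' @param p an `axial_profile` or `mineral_rate_profile`.
#' @param path output CSV path.
#' @param provenance optional named list added to the comment header.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path, provenance = NULL) {
  if (inherits(p, "mineral_rate_profile")) {
    meta <- list(kind = "mineral_rate_profile",
                 mode = attr(p, "mode"),
                 delta_x_mm = attr(p, "delta_x_mm"),
                 smoothed_input = attr(p, "smoothed_input"))
  } else if (inherits(p, "axial_profile")) {
    meta <- list(kind = "axial_profile",
                 gumline_mm = attr(p, "gumline_mm"),
                 voxel_um = attr(p, "voxel_um"),
                 smoothed = attr(p, "smoothed"),
                 window = attr(p, "window"))
  } else {
    abort_if(TRUE, "`p` must be an axial_profile or mineral_rate_profile",
             class = "enamelmat_validation_error")
  }
  meta <- c(meta, provenance)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(header_comments(meta), con)
  utils::write.csv(as.data.frame(p), con, row.names = FALSE)
  invisible(path)
}

#' Read a profile CSV written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @return The reconstructed `axial_profile` or `mineral_rate_profile`.
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  if (identical(meta$kind, "mineral_rate_profile")) {
    structure(df, mode = meta$mode,
              delta_x_mm = as.numeric(meta$delta_x_mm),
              smoothed_input = identical(meta$smoothed_input, "TRUE"),
              class = c("mineral_rate_profile", "data.frame"))
  } else {
    new_axial_profile(df, as.numeric(meta$voxel_um),
                      as.numeric(meta$gumline_mm),
                      smoothed = identical(meta$smoothed, "TRUE"),
                      window = suppressWarnings(as.integer(meta$window)))
  }
}

#' Write / read the hardness CSV dialect
#'
#' Header `animal_id,age_weeks,level,region,side,hv`.
#' @param t hardness data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame with `level` as an ordered
#'   below/at/above factor (read).
#' @export
write_hardness_csv <- function(t, path) {
  cols <- c("animal_id", "age_weeks", "level", "region", "side", "hv")
  abort_if(!all(cols %in% names(t)),
           "hardness table must have columns animal_id,age_weeks,level,region,side,hv",
           class = "enamelmat_validation_error")
  utils::write.csv(t[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hardness_csv
#' @export
read_hardness_csv <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  abort_if(!all(c("age_weeks", "level", "hv") %in% names(t)),
           "not a hardness CSV", class = "enamelmat_format_error")
  abort_if(any(t$hv <= 0), "hv values must be positive",
           class = "enamelmat_validation_error")
  t$level <- factor(t$level, levels = c("below", "at", "above"))
  t
}
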