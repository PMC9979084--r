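# Axial profiling, area filter, smoothing, band means, sample averaging.

# build a tomogram/mask pair with a prescribed per-slice density and
# per-slice enamel voxel count
slab_pair <- function(density_by_slice, voxels_by_slice, voxel_um = 6,
                      nx = 30) {
  nz <- length(density_by_slice)
  vol <- array(0, c(nx, nx, nz))
  m <- array(FALSE, c(nx, nx, nz))
  for (k in seq_len(nz)) {
    n <- voxels_by_slice[k]
    if (n > 0) {
      idx <- seq_len(n)
      sl <- matrix(FALSE, nx, nx); sl[idx] <- TRUE
      m[, , k] <- sl
      v <- matrix(0, nx, nx); v[idx] <- density_by_slice[k]
      vol[, , k] <- v
    }
  }
  list(tom = tomogram(vol, voxel_um), mask = enamel_mask(m, voxel_um))
}

test_that("area filter drops slices below 0.02 mm^2 (556 voxels at 6 um)", {
  # 0.02 mm^2 / (6 um)^2 = 555.6 voxels: 555 drops, 556 stays
  p <- slab_pair(c(2000, 2000, 2000), c(600, 555, 556))
  prof <- axial_profile(p$tom, p$mask, 0.02, gumline_mm = 0)
  expect_equal(nrow(prof), 2)
  expect_equal(prof$x_mm, c(0, 2) * 0.006)
  expect_equal(prof$area_mm2, c(600, 556) * 0.006^2)
  # default threshold is 0.02 mm^2
  expect_equal(formals(axial_profile)$min_area_mm2, 0.02)
})

test_that("profile of a uniform phantom is flat at the plateau", {
  spec <- small_spec(noise_sd = 0)
  r <- render_tomogram(spec, simulate_density_field(spec, 50))
  # interior of the enamel (surface ring excluded) sits exactly at plateau
  sh <- surface_shell(r$mask, 60)
  interior <- enamel_mask(r$mask$voxels & !sh$voxels, spec$voxel_um)
  prof <- axial_profile(r$tomogram, interior, 0.02, gumline_mm = 3)
  expect_true(all(abs(prof$mean_density - spec$rho_plateau) < 1e-9))
})

test_that("profile ignores everything outside the mask", {
  p <- slab_pair(rep(1500, 5), rep(600, 5))
  prof1 <- axial_profile(p$tom, p$mask, 0.02, gumline_mm = 0)
  vol2 <- p$tom$voxels
  vol2[!p$mask$voxels] <- 9999   # garbage outside the mask
  prof2 <- axial_profile(tomogram(vol2, 6), p$mask, 0.02, gumline_mm = 0)
  expect_equal(prof1$mean_density, prof2$mean_density)
  expect_error(axial_profile(p$tom, p$mask, 10, gumline_mm = 0),
               class = "enamelmat_empty_profile_error")
})

test_that("moving average matches hand arithmetic and preserves bounds", {
  p <- slab_pair(1:7 * 100, rep(600, 7))
  prof <- axial_profile(p$tom, p$mask, 0.02, gumline_mm = 0)
  sm <- smooth_profile(prof, 5)
  # interior: plain 5-point means; edges: shrinking symmetric windows
  expect_equal(sm$mean_density, c(100, 200, 300, 400, 500, 600, 700))
  y <- c(5, 1, 9, 3, 7, 2, 8)
  p2 <- slab_pair(y, rep(600, 7))
  sm2 <- smooth_profile(axial_profile(p2$tom, p2$mask, 0.02, gumline_mm = 0), 5)
  expect_equal(sm2$mean_density[3:5],
               c(mean(y[1:5]), mean(y[2:6]), mean(y[3:7])))
  expect_equal(sm2$mean_density[1], y[1])
  expect_equal(sm2$mean_density[2], mean(y[1:3]))
  expect_true(all(sm2$mean_density >= min(y) & sm2$mean_density <= max(y)))
  # a constant profile is a fixed point
  pc <- slab_pair(rep(2000, 9), rep(600, 9))
  smc <- smooth_profile(axial_profile(pc$tom, pc$mask, 0.02, gumline_mm = 0), 5)
  expect_true(all(smc$mean_density == 2000))
  expect_error(smooth_profile(prof, 4), class = "enamelmat_validation_error")
  expect_true(attr(sm, "smoothed"))
  expect_equal(attr(sm, "window"), 5L)
})

test_that("band means average the right half-open slice set", {
  # constant profile: mean = value, sd = 0 for any band
  pc <- slab_pair(rep(2000, 10), rep(600, 10))
  prof <- axial_profile(pc$tom, pc$mask, 0.02, gumline_mm = 0)
  bm <- band_mean(prof, 0, 3)
  expect_equal(unname(bm["mean"]), 2000)
  expect_equal(unname(bm["sd"]), 0)

  # linear profile: band mean equals the brute-force average of the
  # sampled values inside the half-open band
  x_slices <- 0:99 * 0.06
  rho <- 1000 + 100 * x_slices
  pl <- slab_pair(rho, rep(600, 100), voxel_um = 60)
  profl <- axial_profile(pl$tom, pl$mask, 0.02, gumline_mm = 0)
  bml <- band_mean(profl, 0, 3)
  sel <- profl$x_mm >= 0 & profl$x_mm < 3
  expect_equal(unname(bml["mean"]), mean(profl$mean_density[sel]))
  expect_equal(unname(bml["n"]), sum(sel))

  # bands partition: [0,1.5) and [1.5,3) counts sum to [0,3)
  n1 <- band_mean(profl, 0, 1.5)["n"]
  n2 <- band_mean(profl, 1.5, 3)["n"]
  expect_equal(unname(n1 + n2), unname(bml["n"]))

  expect_error(band_mean(profl, 3, 3), class = "enamelmat_validation_error")
  expect_error(band_mean(profl, 50, 60), class = "enamelmat_empty_band_error")
})

test_that("profile averaging aligns, interpolates and reports sample SD", {
  mk <- function(vals) {
    p <- slab_pair(vals, rep(600, length(vals)))
    axial_profile(p$tom, p$mask, 0.02, gumline_mm = 0)
  }
  # identical profiles: mean = input, sd = 0
  p1 <- mk(rep(1500, 6))
  avg <- average_profiles(list(p1, p1, p1))
  expect_equal(avg$mean_density, rep(1500, 6))
  expect_equal(avg$sd, rep(0, 6))

  # three constants: mean 2000, sample SD 1000 at every shared point
  avg2 <- average_profiles(list(mk(rep(1000, 5)), mk(rep(2000, 5)),
                                mk(rep(3000, 5))))
  expect_equal(avg2$mean_density, rep(2000, 5))
  expect_equal(avg2$sd, rep(1000, 5))

  expect_error(average_profiles(list(p1)),
               class = "enamelmat_validation_error")
})
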