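# Synthetic phantom: density field kinematics, rasterisation, generators.

# surface-layer density the renderer should use at a given age
surface_rho <- function(spec, age) {
  ages <- as.numeric(names(spec$surface_rho_by_age))
  approx(ages, spec$surface_rho_by_age, age, rule = 2)$y
}

test_that("density field follows the travelling-front closed form", {
  spec <- small_spec()
  # fully matured limit: front has swept the whole crown
  f <- simulate_density_field(spec, age_weeks = 50)
  expect_true(all(f$rho == spec$rho_plateau))

  # default plateau of mature enamel
  expect_equal(phantom_spec()$rho_plateau, 2083)

  # space-for-time: rho(x, t + dt) = rho(x + v dt, t) analytically
  x <- seq(0, 4, by = 0.01)
  v <- spec$extension_rate_mm_per_wk
  for (dt in c(0.5, 1, 2.2)) {
    lhs <- phantom_density(spec, x, 2 + dt)
    rhs <- phantom_density(spec, x + v * dt, 2)
    expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1)), 1e-9)
  }
})

test_that("density field is monotone in position and age", {
  spec <- small_spec()
  x <- seq(0, spec$crown_length_mm, by = 0.05)
  for (age in c(0.5, 2, 3, 7)) {
    rho <- phantom_density(spec, x, age)
    expect_true(all(diff(rho) >= 0))
    expect_true(all(rho >= 0 & rho <= spec$rho_plateau))
  }
  # non-decreasing in age at a fixed material point
  for (xi in c(0.2, 1.7, 3.9)) {
    rho_t <- phantom_density(spec, xi, seq(0.5, 10, by = 0.25))
    expect_true(all(diff(rho_t) >= -1e-12))
  }
})

test_that("spec invariants are validated", {
  expect_error(phantom_spec(rho_initial = 2100), "rho_plateau",
               class = "enamelmat_validation_error")
  expect_error(phantom_spec(voxel_um = 400, enamel_thickness_mm = 0.3),
               class = "enamelmat_validation_error")
  expect_error(phantom_spec(crown_length_mm = -1),
               class = "enamelmat_validation_error")
  expect_error(simulate_density_field(small_spec(), age_weeks = -2),
               class = "enamelmat_validation_error")
})

test_that("renderer places plateau, surface layer and labels correctly", {
  # noise-free render of a fully matured tooth: every bulk enamel voxel
  # equals the plateau exactly, surface voxels the age-specific density
  spec <- small_spec(noise_sd = 0)
  f <- simulate_density_field(spec, 50)
  r <- render_tomogram(spec, f)
  vals <- r$tomogram$voxels[r$mask$voxels]
  expect_setequal(unique(vals),
                  c(spec$rho_plateau, surface_rho(spec, 50)))

  # at age 2 the surface layer sits at 1644 before noise
  spec2 <- small_spec(noise_sd = 0)
  r2 <- render_tomogram(spec2, simulate_density_field(spec2, 2))
  expect_true(any(r2$tomogram$voxels[r2$mask$voxels] == 1644))

  # labels partition the volume and every enamel voxel is masked
  expect_true(all(r2$labels %in% 0:2))
  expect_identical(r2$labels == 2L, r2$mask$voxels)

  # oversized render is refused
  big <- phantom_spec(max_voxels = 1e4)
  expect_error(render_tomogram(big, simulate_density_field(big, 2)),
               class = "enamelmat_size_error")
})

test_that("renders are deterministic under the seed and unbiased under noise", {
  spec <- small_spec(seed = 11, noise_sd = 50)
  f <- simulate_density_field(spec, 2)
  r1 <- render_tomogram(spec, f)
  r2 <- render_tomogram(spec, f)
  expect_identical(r1$tomogram$voxels, r2$tomogram$voxels)
  expect_identical(r1$mask$voxels, r2$mask$voxels)

  # mean of noisy enamel voxels matches the noise-free mean within 3 SE
  spec0 <- small_spec(seed = 11, noise_sd = 0)
  r0 <- render_tomogram(spec0, simulate_density_field(spec0, 2))
  n <- sum(r0$mask$voxels)
  se <- 50 / sqrt(n)
  expect_lt(abs(mean(r1$tomogram$voxels[r1$mask$voxels]) -
                  mean(r0$tomogram$voxels[r0$mask$voxels])), 3 * se)
})

test_that("hardness table generator honours its design", {
  d0 <- hardness_design(residual_sd = 0, seed = 5)
  t0 <- make_hardness_table(d0)
  mu <- d0$cell_means[cbind(as.character(t0$age_weeks),
                            as.character(t0$level))]
  expect_equal(t0$hv, unname(mu))

  # defaults carry the pre-/post-eruptive anchors of the youngest animals
  expect_equal(unname(d0$cell_means["2", "below"]), 224)
  expect_equal(unname(d0$cell_means["2", "above"]), 344)

  # grand mean of a noisy table close to the design mean
  d1 <- hardness_design(residual_sd = 40, replicates_per_cell = 20, seed = 2)
  t1 <- make_hardness_table(d1)
  se <- 40 / sqrt(nrow(t1))
  expect_lt(abs(mean(t1$hv) - mean(d1$cell_means)), 3 * se)

  # determinism and validation
  expect_identical(make_hardness_table(d1)$hv, t1$hv)
  expect_error(hardness_design(replicates_per_cell = 1),
               class = "enamelmat_validation_error")
  expect_error(hardness_design(cell_means = matrix(-1, 2, 2,
                                                   dimnames = list(c("2", "4"), c("below", "at")))),
               class = "enamelmat_validation_error")
})

test_that("fluorescein stack generator encodes exponential penetration", {
  s <- make_fluorescein_stack(depth_constant_um = 50, surface_intensity = 800,
                              noise_sd = 0, dim = c(60L, 8L, 4L),
                              voxel_um = 5)
  prof <- s$voxels[, 1, 1]
  # at d = depth constant the noise-free intensity is surface/e
  expect_equal(prof[1 + 50 / 5], 800 * exp(-1), tolerance = 1e-12)
  # near-zero depth constant: only the surface row is non-negligible
  s0 <- make_fluorescein_stack(depth_constant_um = 1e-3,
                               surface_intensity = 100, noise_sd = 0,
                               dim = c(10L, 4L, 2L), voxel_um = 5)
  expect_equal(s0$voxels[1, 1, 1], 100)
  expect_lt(max(s0$voxels[-1, , ]), 1e-6)
  # noisy stacks are non-negative and seeded
  s1 <- make_fluorescein_stack(50, 800, noise_sd = 60, seed = 9)
  expect_true(all(s1$voxels >= 0))
  expect_identical(make_fluorescein_stack(50, 800, noise_sd = 60,
                                          seed = 9)$voxels, s1$voxels)
})
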