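# enamelmat

Micro-CT densitometry of post-eruptive enamel maturation.

Teeth in fast-developing mammals erupt before their enamel is fully
mineralised: a hypomineralised, porous surface layer finishes maturing *in
the mouth*. `enamelmat` quantifies that process from calibrated micro-CT
volumes of developing incisors, and ships a synthetic tooth-phantom
generator so the entire pipeline is testable without scan data:

* **Segmentation & reorientation** — classical enamel segmentation
  (density window + closing + component filter, with a Dice ≥ 0.95 contract
  against phantom ground truth) and principal-axis alignment of the tooth's
  long axis.
* **Density profiling** — axial (per-slice) mean mineral density with a
  0.02 mm² area filter and 5-point moving-average smoothing; outer 30 µm
  surface-shell profiles via an exact Euclidean distance rule that excludes
  the dentin–enamel junction; band means relative to the gingival-emergence
  plane.
* **Mineral-addition rate** — the spatial gradient statistic

  $$\Delta\rho(x) = \frac{\rho_{x+\delta x}-\rho_x}{\delta x},
  \qquad \delta x = 1\ \text{mm by default},$$

  a space-for-time proxy for the temporal maturation rate (absolute mode in
  mg_HA/cm³ per mm; a relative mode normalised by $\rho_x$ is equally
  first-class and the mode is always recorded).
* **Microhardness statistics** — Vickers HV from indent geometry
  (HV = 1854.4 P/d²) and two-way age × location ANOVA (Type III,
  sum-to-zero contrasts) with Tukey HSD comparisons.
* **Surface porosity** — fluorescein penetration depth from confocal-style
  stacks: maximum intensity projection, depth-binned intensity profile, and
  exponential depth-constant fitting.

The phantom generator embodies the maturation kinematics the analysis
assumes — a linear density ramp from the cervical margin travelling with
tooth extension, so ρ(x, t+Δt) = ρ(x+vΔt, t) exactly — plus an
age-dependent hypomineralised 30 µm surface layer and Gaussian imaging
noise. See the methods vignette (`vignettes/enamel-maturation.Rmd`) for the
model, parameter defaults, and what phantom-based validation does and does
not demonstrate.

## Worked example

```r
library(enamelmat)

spec <- phantom_spec(voxel_um = 24, noise_sd = 50, seed = 1)
field <- simulate_density_field(spec, age_weeks = 2)   # 2-week-analogue tooth
phantom <- render_tomogram(spec, field)

mask <- segment_enamel(phantom$tomogram, lo = 1400, hi = 2600)
dice(mask, phantom$mask)
#> 0.9999

shell    <- surface_shell(mask, depth_um = 30)
interior <- enamel_mask(mask$voxels & !shell$voxels, spec$voxel_um)
bulk <- smooth_profile(axial_profile(phantom$tomogram, interior, gumline_mm = 13), 5)
surf <- smooth_profile(axial_profile(phantom$tomogram, shell,    gumline_mm = 13), 5)

round(band_mean(bulk, from_mm = 1, to_mm = 4), 1)   # mature plateau band
#>   mean     sd      n
#> 2069.4    0.4  125.0
round(band_mean(surf, from_mm = 0, to_mm = 3), 1)   # erupted surface band
#>   mean     sd      n
#> 1643.7    1.6  125.0

rate <- mineral_addition_rate(bulk, delta_x_mm = 1, mode = "absolute")
mean(rate$rate[rate$x_mm >= 3 & rate$x_mm <= 11])
#> 15.9   # mg_HA/cm^3 per mm on the maturation ramp
```

The recovered surface band (1643.7) sits on the generator's 2-week surface
density (1644); the plateau band (2069.4) recovers the 2083 plateau to
0.7% — the residual being partial mixing of the hypomineralised ring at a
24 µm pitch — and the ramp rate (15.9) recovers the generator's 16.4
mg_HA/cm³ per mm slope within 3%.

Hardness tables follow the same pattern:

```r
tbl <- make_hardness_table(hardness_design(seed = 5))
two_way_anova(tbl, "age_weeks", "level", "hv")
#> Two-way ANOVA (Type III SS, sum-to-zero contrasts)
#>   age_weeks                    F(2, 18) = 11.5, p = 0.000615
#>   level                        F(2, 18) = 2.46, p = 0.1135
#>   age_weeks:level              F(4, 18) = 2.05, p = 0.1305
```

Hardness increases with age (the generated design ranges from 224 HV,
2-week pre-eruptive, to 372 HV) while location and interaction stay below
the detection threshold at this sample size.

## Command line

A thin wrapper over the same functions lives at `inst/cli/enamelmat.R`:

```sh
Rscript inst/cli/enamelmat.R simulate --age 2 --voxel-um 24 \
    --out-volume tooth.nii.gz --out-mask truth.nii.gz
Rscript inst/cli/enamelmat.R segment --in tooth.nii.gz --lo 1400 --hi 2600 --out mask.nii.gz
Rscript inst/cli/enamelmat.R run --config pipeline.yaml
```

`run_pipeline()` / `run` execute segment → reorient → profile → shell →
smooth → band means → rate and write all artifacts plus a JSON report;
reports are byte-identical across reruns of the same config and seed.

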