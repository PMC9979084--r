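---
title: "Quantifying post-eruptive enamel maturation from micro-CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying post-eruptive enamel maturation from micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enamelmat)
```

## The measurement problem

Enamel erupts into the mouth before it is finished. In fast-developing
species the crown forms in weeks, and a substantial part of mineral uptake —
the maturation phase in which protein is removed and hydroxyapatite packs the
rod structure — happens *after* eruption, fed from the oral environment
through a still-porous surface. Three observables track this process:

* **axial mineral density**: the mean density of the enamel cross-section as
  a function of position along the cervical–occlusal axis, from calibrated
  micro-CT (mg_HA/cm³);
* **surface-shell density**: the same statistic restricted to the outer
  30 µm of enamel, where post-eruptive uptake concentrates;
* **microhardness and dye penetration**: Vickers indentation and fluorescein
  ingress as functional correlates of density and porosity.

Measuring a *rate* of mineralisation directly would require imaging the same
tooth repeatedly. The pipeline instead uses a space-for-time substitution:
in a steadily extending tooth, the section at position $x$ (measured from
the cervical margin, the newest enamel) will, after a time lag set by the
extension rate $v$, resemble the section now at $x + \delta x$. The spatial
gradient of the axial profile is therefore a proxy for the temporal
maturation rate:

$$\Delta\rho(x) = \frac{\rho_{x+\delta x} - \rho_x}{\delta x}
\quad\text{(absolute mode, mg\_HA/cm}^3\text{ per mm)},$$

computed by default with $\delta x = 1$ mm. A second, *relative* mode
divides additionally by $\rho_x$ (units: per mm). Published magnitudes for
this class of statistic correspond to the un-normalised difference, but a
normalised reading of the defining formula is equally defensible, so
`mineral_addition_rate()` implements both modes as first-class citizens,
defaults to absolute, and always records the mode and $\delta x$ in its
output — it never chooses silently. $\delta x$ is applied on physical
distance with linear interpolation, which makes the statistic independent of
the sampling pitch.

Interpretation caveat: $\Delta\rho$ conflates the true maturation rate with
growth and eruption kinematics. It is a snapshot statistic; converting it to
a per-week rate requires an extension rate measured independently, which the
package deliberately does not estimate.

## Pipeline stages and their parameters

The standard order is segmentation → reorientation → profiling →
surface-shell profiling → smoothing → band means → rate
(`run_pipeline()` wires them together and writes a JSON report).

**Segmentation** (`segment_enamel()`). A classical reference chain —
density window `[lo, hi]` (defaults 1400–2600 mg_HA/cm³), one pass of
6-connected binary closing, removal of connected components below
`min_component_voxels`. This replaces learned segmenters deliberately: the
downstream statistics only require a mask meeting a Dice ≥ 0.95 contract
against ground truth, which the threshold chain achieves on phantoms at
noise SD 50. The mask contract, not the segmenter, is the module boundary,
so a trained model can be slotted in later. Ties between equally large
components keep all of them (worn enamel may be split). Erosion treats
out-of-volume neighbours as foreground, so structures touching the volume
face (the cut cervical end of a scan) are not nibbled at the face.

**Reorientation** (`reorient_long_axis()`). The principal axis of the
mask's second-moment tensor is rotated onto the slice axis; density is
resampled trilinearly, the mask by nearest neighbour. The axis sign is
chosen so the cervical margin — the low-density end under the maturation
ramp — sits at low slice index; with no density gradient the far-from-
centroid end (the cusp) points up. If the two largest moments are within 5%
the orientation is refused as ambiguous rather than guessed.

**Axial profile** (`axial_profile()`). Mean density and cross-sectional
area per slice. Slices with area < 0.02 mm² are dropped *before* smoothing
— near the cervical margin the enamel cross-section approaches the voxel
size and partial-volume effects dominate; dropped slices are absent from
the profile, never zero-filled. Axial position is reported in mm from the
cervical-most enamel-containing slice (0-based physical convention:
slice $i$ sits at $(i + 0.5)\,\times$ pitch). The gumline position is a
required user landmark, mirroring physical marking of the gingival
emergence plane at dissection; no automatic detection is attempted.

**Surface shell** (`surface_shell()`, default 30 µm). Enamel voxels within
`depth_um` (Euclidean, voxel-centre metric) of the *exterior* background —
the component reachable from the volume corners. Interior cavities,
including the dentin core, are excluded from the distance reference, so
the dentin–enamel junction never contributes "surface" voxels. Note the
metric's granularity: at a 48 µm pitch no voxel centre lies within 30 µm of
another, so a 30 µm shell is empty; shell analyses need a pitch of at most
24 µm (the function warns when `depth_um` is below half the pitch).

**Smoothing** (`smooth_profile()`, window 5). Centred moving average;
edges use shrinking symmetric windows (widths 1, 3, 5, …), which preserves
profile length and linear trends and introduces no edge bias. The window is
applied to whatever grid the profile carries, and the grid pitch is
recorded alongside.

**Band means** (`band_mean()`). Bands are half-open $[{\rm from},{\rm to})$
relative to the gumline so adjacent bands partition the axis; the band 0–3
mm above the gumline is the standard reporting band for erupted surface
enamel.

**Hardness** (`vickers_hv()`, `two_way_anova()`, `tukey_hsd()`).
HV $= 1854.4\,P/d^2$ with $P$ in gram-force and $d$ the mean diagonal in
µm; values outside 10–600 HV are flagged, not rejected. The factorial
analysis uses Type III sums of squares with sum-to-zero contrasts — the
convention of the GUI statistics packages such studies are analysed in —
and reports Tukey-adjusted pairwise comparisons. Published degrees of
freedom for this kind of design imply analysis of per-animal site means
rather than individual indents; the `aggregate` argument performs exactly
that reduction, and no attempt is made to reverse-engineer a more specific
aggregation. With zero residual variance the F statistics are reported as
infinite and flagged; zero-effect sums of squares report F = 0, p = 1.

**Fluorescein** (`max_intensity_projection()`, `penetration_depth()`,
`fit_depth_constant()`). Dye-penetration assessment in maximum intensity
projections is made quantitative here: mean intensity per one-pixel depth
bin from a straight surface line, surface intensity normalised as the mean
of the first three bins, monotone smoothing (running maximum from deep to
shallow) before thresholding so speckle cannot terminate the search, and a
reported `depth_at_fraction` (default fraction $1/e$). These definitions
extend the underlying qualitative protocol and are labelled as such.
Cross-specimen comparisons should use fitted depth constants, not raw
intensities, since staining and acquisition are not normalised across
specimens.

## What the phantom generator emulates

`phantom_spec()` + `simulate_density_field()` + `render_tomogram()` produce
fully synthetic, deterministic test volumes: an axisymmetric enamel shell
over a dentin core, with

* a **travelling maturation front**: bulk density rises linearly from
  `rho_initial` at the cervical margin to `rho_plateau` over
  `maturation_ramp_mm`, and the front advances at the extension rate, so
  $\rho(x, t+\Delta t) = \rho(x + v\Delta t, t)$ holds *exactly* in the
  closed form — the space-for-time premise is true by construction and the
  pipeline's recovery of it is testable end-to-end;
* a **hypomineralised 30 µm surface layer** whose density is an
  age-interpolated table (defaults 1644 / 1977 / 1959 mg_HA/cm³ at 2 / 4 /
  16 weeks — the reported progression for erupted porcine incisor surface
  enamel);
* **additive Gaussian noise** (default SD 50 mg_HA/cm³) added voxel-wise.

Default geometry and kinematics (chosen once as a realistic porcine
first-incisor scale, and not tuned thereafter): crown 18 mm, enamel
thickness 0.3 mm over a 0.8 mm dentin core, dentin at 1200 mg_HA/cm³,
plateau 2083 mg_HA/cm³, cervical bulk density 1870 mg_HA/cm³, ramp 13 mm
(slope ≈ 16.4 mg_HA/cm³ per mm, the scale of reported near-cervical
mineral-addition rates), gumline at 13 mm, extension 2.5 mm/week, front at
the margin at 2 weeks (so a 16-week render is uniformly mature). The spec
default pitch is 6 µm — the acquisition pitch this pipeline targets — but
tests and examples render at 24–48 µm to keep volumes near 10⁶–10⁷ voxels;
`max_voxels` guards against accidental full-resolution renders.

Deliberate non-realism, hence what passing tests do *not* show: geometry is
a shell-on-cylinder with a tapered cervical collar and an occlusal cap, not
an anatomical incisor; noise is Gaussian (no Poisson statistics, beam
hardening, rings or partial-volume blur); porosity is not resolved; the
surface layer has a sharp inner boundary; eruption status is supplied via
`gumline_mm`, not simulated. Parameter-recovery results on phantoms
demonstrate the estimators' correctness under these assumptions, not
robustness to scanner physics.

Two rasterisation details matter for interpretation. First, the enamel
collar is floored at two voxels so the shell ring is complete on every
slice and the dentin core is topologically enclosed — this is what lets the
exterior-component rule exclude the DEJ. Second, where the collar tapers
and at the occlusal cap the surface-ring share of the cross-section changes
along $z$; the whole-enamel profile of even a uniformly mature phantom
therefore drifts slightly there, and null-rate checks are evaluated on the
mid-crown where shell geometry is constant. Recovery protocols separate the
compartments explicitly: plateau and ramp slope are measured on the
interior profile (mask minus 30 µm shell) and surface density on the shell
profile, since the whole-enamel mean mixes ~9% of hypomineralised ring into
the bulk signal at a 24 µm pitch — a property of the phantom's thin shell,
not an estimator defect.

The companion generators mirror the tabular data: `make_hardness_table()`
draws balanced age × gumline-location HV tables around cell means anchored
at the reported extremes (224 HV pre-eruptive at 2 weeks, 344 HV
post-eruptive, up to 372 HV at 4 weeks), and `make_fluorescein_stack()`
produces exponential-decay stacks whose depth constant is the recoverable
ground truth.

## Numerical choices

* Distances are voxel-centre Euclidean, scaled by the isotropic pitch.
* The shell test enumerates all integer offsets within the depth radius
  (capped at the volume diameter); connected components use
  `igraph::components` on the 6-adjacency graph of foreground voxels.
* Calibration (`calibrate_density()`) is ordinary least squares through the
  supplied (raw, density) pairs; two distinct pairs are the minimum and
  degenerate (constant-raw) pairs are an error.
* Trilinear resampling reads out-of-volume voxels as zero; masks are
  re-binarised after nearest-neighbour resampling.
* Ties in component size are kept; ties in Tukey comparisons follow
  `stats::TukeyHSD`.
* Profile averaging (`average_profiles()`, `average_rates()`) aligns at
  the cervical margin, restricts to the shared axial range, interpolates
  onto the first profile's grid and reports the pointwise sample SD;
  profiles with disjoint ranges, or rates with mismatched mode or
  $\delta x$, are errors rather than silent coercions.
* All generators take explicit seeds and restore the caller's RNG state;
  identical specs render bit-identical volumes, and `run_pipeline()`
  reports are byte-identical across reruns of the same config.

## Problem sizes used by the test-suite and acceptance script

Phantom checks render at 24 µm (18 mm crown, ≈ 7 × 10⁶ voxels) for
parameter recovery and at 48 µm (6 mm crown, ≈ 3 × 10⁵ voxels) for
segmentation sweeps; the shell-versus-enumeration suite uses random blob
masks up to 32³; ANOVA calibration uses 1000 null replicates of a 27-row
table; fluorescein round-trips use 120 × 48 × 12 stacks at SNR 10. These
sizes were chosen so each property is measured well inside its tolerance.

## Known limitations

* Radial (DEJ-to-surface) profiles, eruption-speed estimation, and
  conversion of $\Delta\rho$ to per-week rates are out of scope.
* The exterior-component rule assumes the enamel mask encloses interior
  cavities; a mask with a broken ring lets the exterior leak inside and
  the shell will include DEJ voxels (the phantom's collar floor exists to
  keep this testable).
* TIFF I/O carries no pitch and stores intensities relative to an explicit
  scale; NIfTI is the lossless default.
* Curved-surface geodesic penetration depth is not implemented; the
  fluorescein metric assumes a straight surface line.
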