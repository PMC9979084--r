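Package: enamelmat
Title: Micro-CT Densitometry of Post-Eruptive Enamel Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies enamel maturation from calibrated micro-CT volumes of
    developing teeth: classical enamel segmentation and long-axis
    reorientation, axial (per-slice) and outer-surface-shell mineral-density
    profiles with area filtering and moving-average smoothing, the
    mineral-addition-rate statistic (the spatial density gradient used as a
    space-for-time proxy for the maturation rate), Vickers microhardness
    statistics with two-way ANOVA and Tukey multiple comparisons, and
    fluorescein penetration-depth profiling of surface porosity. Includes a
    fully parameterised synthetic tooth-phantom generator (axisymmetric enamel
    shell over a dentin core with a travelling maturation front, a
    hypomineralised surface layer and Gaussian imaging noise) so that every
    stage of the pipeline is testable without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    igraph,
    car
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
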