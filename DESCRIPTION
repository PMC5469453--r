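Package: hemorobust
Title: Hemodynamic Indicators and Resolution-Robustness Statistics for
    Cerebral Aneurysm Flow Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing machinery for computational studies of
    cerebral-aneurysm hemodynamics. Computes the standard wall-shear-stress
    based indicators (time- and space-averaged WSS, maximum WSS, oscillatory
    shear index, low shear area, shear concentration index, WSS gradient and
    time derivative), velocity-based indicators (viscous dissipation ratio,
    inflow concentration index) and morphological indices (volume,
    non-sphericity index, aspect ratio) on labeled triangulated surfaces and
    tetrahedral meshes. Provides pulsatile boundary-condition constructions
    (Womersley inflow profiles, Murray's-law resistance outlets, waveform
    dampening), mesh-resolution and timestep arithmetic, generators for
    idealized aneurysm geometries and analytic flow fields with known
    indicator values, a paired coarse/fine synthetic cohort emulator, and the
    agreement statistics used in grid-refinement robustness studies
    (Pearson correlation, mean relative difference, logarithmic Bland-Altman
    analysis, normality-gated two-group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
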