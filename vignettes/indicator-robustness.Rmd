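---
title: "Hemodynamic indicators and their robustness to mesh resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemodynamic indicators and their robustness to mesh resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemorobust)
```

## The problem

CFD studies of cerebral aneurysms reduce a space–time velocity field to a
handful of scalar indicators — averaged and maximal wall shear stress,
oscillation and concentration indices, spatial and temporal WSS
derivatives — and correlate them with clinical outcomes such as rupture.
Because these indicators integrate or differentiate the raw solution, their
convergence under mesh refinement is not that of the velocity: integration
gains accuracy, differentiation loses it. A cohort-level conclusion may
therefore rest on indicator values that are individually unconverged.
`hemorobust` implements the full post-solver chain needed to study this:
the indicator definitions, the boundary-condition constructions and
resolution arithmetic that define a two-resolution study, generators for
synthetic inputs with known ground truth, and the coarse-versus-fine
agreement statistics.

The Navier–Stokes solve itself is out of scope: fields enter as data
(`surface_series`, `volume_series`) or as analytic constructions.

## Data model and conventions

Surfaces are triangulated walls with exactly one region label per face:
`sac` (the dome Γa), `neck` (the surface separating dome from parent
vessels — a delineated surface, not necessarily a plane), `parent`,
`near_vessel`, `other`. Volumes are tetrahedral meshes labeled `aneurysm`
(Ωa) and `near_vessel` (Ωnv). Coordinates are millimetres, WSS is Pa,
velocity m/s, time seconds; indicators then come out in the units in which
they are conventionally reported (Pa, Pa/mm, Pa/s, mm³). Converters belong
at the I/O boundary, never inside the indicator code.

Time series live on a uniform grid spanning one cycle `[T0, T1]`, with the
first and last samples at the same phase. All time averages use the
composite trapezoidal rule, which on this periodic grid is spectrally
accurate for smooth integrands (it annihilates every resolvable harmonic:
a `2 + sin(ωt)` magnitude averages to exactly 2).

Vertex-centered fields are resampled to faces by the arithmetic mean of
the three corner values; the face-centered form is canonical. The surface
integral of a per-face field is the midpoint rule `Σ f·area`, exact for
fields linear over each face after that resampling.

The near-vessel band is labeled by Dijkstra shortest paths on the surface
edge graph (Euclidean edge weights), sourced at the neck boundary
vertices, with a 10 mm default cutoff — the conventional 1 cm near-vessel
domain. Exact polyhedral geodesics are deliberately not used: the edge
graph overestimates distances by at most one edge-length factor, which is
immaterial at band widths of ~50 edges, and keeps the operation linear in
mesh size. Where a mesh has no neck faces, the sac/non-sac interface
stands in for the neck curve. Whether the study convention measures the
band from the neck boundary curve or the neck barycenter is not decidable
from the usual descriptions; the boundary curve is used because it makes
the cutoff a true surface distance.

## Indicator definitions and numerical choices

* **AWSS / MWSS** — sac-area average, and sac maximum, of the
  time-averaged magnitude `mean|τ|`. The time average sits *inside* the
  max; a space–time maximum (`max` over both face and instant) is
  available as `mwss(..., variant = "space_time")` because both readings
  appear in the literature.
* **OSI** — `½(1 − |mean τ| / mean|τ|)` averaged over the sac. The
  numerator is the magnitude of the time-averaged *vector*; by the
  triangle inequality OSI ∈ [0, ½]. Faces with `mean|τ| = 0` would divide
  by zero; they contribute 0 (a stagnant wall carries no directional
  oscillation), which keeps the bound intact.
* **LSA** — the area fraction of the sac with `mean|τ|` strictly below
  0.1 × a reference WSS. The reference defaults to the case's own AWSS;
  the older convention of a parent-artery reference is available through
  the `reference` argument. Ties fall outside the low-shear set.
* **SCI** — at each instant, the high-shear set H collects faces with
  `|τ|` strictly above the area-weighted mean plus one area-weighted SD
  over the sac; SCI is the time average of `(Fh/Fa)/(Ah/Aa)`. The
  threshold is not standardized in print; mean + 1 SD over the sac is
  implemented as the default with the number of SDs and the reference
  region (`sac` or `near_vessel`) configurable. Instants with an empty H
  contribute 0 rather than being dropped, so the time normalization
  `1/(T1−T0)` is preserved; the same convention applies to ICI instants
  with no inflow.
* **VDR** — time average of the ratio of volume-averaged dissipation
  density `(2μ/ρ)‖ε‖²` in Ωa to Ωnv, with the strain rate ε computed
  cell-wise from the linear shape functions of each tetrahedron. A
  vanishing denominator at any sampled instant is an error (the ratio is
  ill-posed), not a silent skip.
* **ICI** — the neck-normal velocity is supplied directly
  (`ici(u_neck, neck_area, qpa, times)`) rather than interpolated from
  the volume field; any interpolation scheme would otherwise dominate the
  operation's error budget. Retrograde parent flow is rejected.
* **WSSG** — each Cartesian component of τ is interpolated linearly over
  the triangle from vertex values and differentiated in-plane; the
  default norm is the Frobenius norm of the resulting tangential vector
  gradient, with the gradient of `|τ|` as a configurable alternative
  (`norm = "magnitude"`) since printed formulas rarely disambiguate the
  two. The operator is exact for linear fields on planar meshes and
  frame-invariant. Face-centered input is rejected with instructions to
  resample: a piecewise-constant field has no within-face gradient.
* **TDWSS** — central differences of `|τ|` in time with periodic
  wrap-around. For smooth magnitudes the discretization error is second
  order; where `|τ|` has kinks (sign reversals of a component) it drops
  to first order, which is why the reversing-field tests carry a wider
  tolerance than the smooth offset-sine test.
* **Morphology** — sac volume by the divergence theorem over the closed
  (dome + neck) surface, with closedness and orientation consistency
  checked explicitly; NSI = 1 − (18π)^{1/3}V^{2/3}/A with A the *dome*
  area only (the neck is the boundary between dome and vessel, not part
  of the dome), which makes NSI exactly 0 for a hemispherical dome;
  AR = depth / neck width with depth the maximum sac-vertex distance to
  the least-squares neck-boundary plane (dome side) and width the
  equivalent-circle diameter `2√(Aneck/π)` (maximum chord available as an
  option). Depth and width are conventions, flagged as such — studies
  rarely state their exact operationalization.

## Boundary conditions and resolution arithmetic

The inflow model is the classical pulsatile pipe-flow (Womersley)
solution: the zeroth harmonic is the Poiseuille parabola and each higher
harmonic the Bessel-function profile with
Λ = i^{3/2}·α_n, α_n = R√(nω/ν). Complex J₀/J₁ are evaluated by power
series, accurate to round-off for the |Λ| ≲ 30 range that physiological
Womersley numbers produce (α ≈ 2.85 for R = 2 mm, ν = 3.45·10⁻³/1056 m²/s,
T = 0.949 s). Amplitudes are set from the discrete Fourier coefficients of
the waveform so the cross-sectional flux reproduces the (band-limited)
waveform exactly; the profile is scaled so the cycle-mean section-average
velocity equals the target (0.27 m/s by default, matching a 245 ml/min
mean flow in a 2 mm-radius vessel).

The built-in `carotid_waveform()` is a synthetic stand-in: five harmonics
with fixed relative amplitudes and phases that qualitatively resemble an
internal-carotid pulse (sharp systolic upstroke, dicrotic notch). Because
measured waveforms are typically published as figures rather than tables,
a parameterized generator was chosen over digitized samples; everything
downstream (flux reproduction, dampening, profile limits) is
waveform-independent. `dampen_pulsatility()` contracts the waveform about
its mean — 15% by default, the conventional allowance for pulse dampening
along the carotid siphon between measurement site and middle cerebral
artery.

Outlets follow Murray's principle of minimum work: resistances
proportional to the inverse cube of the radius (`p_i = K Σr³/r_i³ · flux`,
K = 10⁹ kg m⁻⁴ s⁻¹), which a lumped-network solve shows distributes flow
as r³. The network solve is performed in units of K to keep the system
well-conditioned.

Two unit/convention pitfalls are resolved explicitly. Blood density is
taken as 1056 kg/m³ (1.056 g/cm³) — the value sometimes appears misprinted
with impossible units in the literature. Per-cycle timestep counts of
8000 (coarse, h = 0.18 mm) and 23000 (fine, h = 0.13 mm) are interpreted
as counts per cardiac cycle: that reading reproduces a Courant number of
0.99 ≤ 1 at 1.5 m/s on the coarse mesh, whereas a two-cycle-total reading
violates the bound. The boundary-layer schedule (total 0.3 h, 4 sublayers,
ratio 0.6 → innermost ≈ 0.03 h) and the effective resolution of quadratic
elements (h/2; 8 linear elements per quadratic tetrahedron) complete the
sizing arithmetic.

## Synthetic data: what it emulates, and what it does not

Patient aneurysm geometries in the relevant databases are not public, so
every input is generated with known ground truth.

The **idealized geometry** is a spherical-cap sac seated on the end of a
cylindrical vessel, with the neck disc as an interior surface. This
placement (rather than a sidewall attachment) keeps the surface watertight
without boolean mesh merging, and makes dome area (2πr² for the
hemisphere), cap volume, depth (Rs + √(Rs² − Rn²)) and AR available in
closed form. Construction is fully deterministic. The aneurysm volume mesh
fans the dome faces to the neck center (valid because the cap solid is
convex), the vessel lumen is a layered prism mesh split into tetrahedra.

The **analytic WSS patterns** (`uniform`, `reversing`, `offset_sine`,
`spot`, `ramp`, `womersley`) each return the field together with a record
of the indicator values it must produce, computed by closed form or dense
quadrature — never by the code under test. Tests compare the pipeline
against that record.

The **synthetic cohort** emulates the statistical structure of a
38-case study (13 ruptured / 25 unruptured): per-indicator lognormal
magnitudes whose log-SD of about 2 spans roughly three orders of magnitude
(2¹¹) for the wide-ranging indicators (LSA, WSSG, TDWSS); coarse values
obtained from fine ones by a systematic bias times contaminated lognormal
noise (5% of cases get a 4× inflated noise SD — the outliers conspicuous
in agreement plots); a multiplicative rupture-group shift per indicator;
and an exact-zero floor for LSA that produces the handful of zero cases
which force the zero-pair exclusion rule downstream.

Calibration is part of the generator, not of any test: the systematic bias
is solved in closed form so the expected mean relative difference equals
the target d, and the noise SD is solved by a Monte-Carlo oracle so the
*expected finite-sample* Pearson correlation at n = 38 equals the target
r. The distinction matters: on heavy-tailed data the population
correlation lies well below the expectation of the n = 38 sample
statistic, and a published r is the latter. Per-indicator targets follow
the reported robustness ordering — OSI worst (r ≈ 0.83), the gradient
indicators next (WSSG ≈ 0.91, TDWSS ≈ 0.93), the integral indicators
above 0.95, morphology exactly reproduced (r = 1, d = 0, computed once
per case independent of flow resolution).

What the cohort does **not** emulate: real indicator values are produced
by one flow field per case, so indicators are mutually correlated
(LSA–SCI, AWSS–VDR, and so on); the generator draws indicators
independently, so cross-correlation structure is exercised only
mechanically. Nor does multiplicative-lognormal noise capture
resolution-error structure that depends on the geometry itself. Passing
statistical-recovery tests therefore demonstrates that the *estimators*
faithfully recover a known generative truth at study scale — not that real
coarse meshes behave lognormally.

## Agreement and group statistics

For each indicator, coarse-vs-fine agreement is summarized by the Pearson
correlation over **all** pairs, and by the mean relative difference
`d = mean((c_i − f_i)/f_i)` and the logarithmic Bland–Altman plot over the
pairs remaining after zero-pair exclusion (either member zero → excluded
and logged; correlation is unaffected by the rule). Bland–Altman
coordinates are `y = log2(c/f)` and `x = log2(√(cf)/max(fine))`, so y
reads directly in doublings of disagreement and x = 0 marks the largest
case; the abscissa formula is a package convention (log geometric mean),
as published plots rarely print one. Limits of agreement are
`mean(y) ± 1.96 sd(y)`.

Rupture-group comparisons use a normality gate: Shapiro–Wilk on each group
at α = 0.05; if neither rejects, a two-tailed two-sample t-test (classical
equal-variance Student form, since that is what "t-test" means absent
qualification; Welch via `var_equal = FALSE`), otherwise a two-sided
Mann–Whitney U computed with the normal approximation and tie correction,
appropriate at n ≈ 38. The gate is applied per group — whether pooled
residuals would be more faithful to any given study is undecidable from
typical methods text, so the choice is documented here. No
multiple-testing correction is applied, matching standard practice in this
literature. Cross-correlation matrices flag two-sided p < 0.05 and
p < 0.001; constant columns are reported as missing rather than silently
dropped.

## Problem sizes and tolerances

The test and acceptance runs use: icosphere subdivisions 1–4 (80–20 480
faces); idealized geometries at 0.2–0.5 mm edge length (≈ 3 000–25 000
faces); tube volume meshes at 0.25–0.4 mm (≈ 10⁴–10⁵ cells); 5–301 time
samples per cycle; 500 cohort replicates for sampling bands and 2 000
replicates for the gated-test size check. These sizes put every closed
form within its quoted tolerance (1% for first-order-converging surface
quantities at the fine settings, 2% for tetrahedral dissipation, 10⁻⁶
relative for Womersley flux, 10⁻¹² for Murray splits) while keeping the
full suite under a minute of compute. Convergence assertions always
compare two refinement levels rather than trusting a single mesh.

## Known limitations

* No Navier–Stokes solver, mesh generation, smoothing or segmentation;
  XDMF/HDF5 time-series I/O is not provided (STL and VTK XML are).
* The surface-gradient operator assumes vertex-centered input and a
  reasonably smooth triangulation; on very anisotropic meshes WSSG
  inherits the mesh quality, as gradient-based quantities do in general.
* TDWSS convergence degrades to first order at magnitude kinks
  (flow-reversal instants).
* The cohort generator's independence across indicators (above) limits
  what its cross-correlation matrices can validate.
* Exact geodesics, pressure-based indicators and aneurysm-formation
  indices (AFI, GON) are intentionally absent.
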