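---
title: "Quantifying nuclear shape, envelope permeability and lamina mechanics with nucleomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear shape, envelope permeability and lamina mechanics with nucleomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomech)
```

## Scope and scientific setting

Mesenchymal stem cells cultured on flat glass spread and flatten their
nucleus into a lens-like ellipsoid; grown inside a 3D lattice microscaffold
(a "Nichoid") or treated with cytochalasin-D on glass, intracellular actin
tension drops and the nucleus rounds up. This package implements the
quantitative analyses that connect that change of shape to
mechanotransduction readouts:

* nuclear contour extraction and spline-based curvature profiling of the
  equatorial plane;
* an ellipsoidal nuclear shape model with the meridian/parallel curvature
  decomposition `Km`, `Keq` and the combined curvature
  `K = sqrt(Keq * Km)`;
* single-molecule tracking near the nuclear envelope: spot detection,
  greedy nearest-neighbour linking, classification of envelope-crossing
  events inside a 5-pixel analysis band, and the crossing fraction as a
  function of the local curvature radius with a weighted linear fit and a
  permutation check;
* fluorescence intensity morphometry: the coefficient of variation of
  line-ROI intensities (chromatin homogeneity), the edge/interior ratio
  beta, normalized major-axis lamin profiles with a two-segment linear fit
  (edge slope alpha and lamina occupancy), structure-tensor actin
  directionality, local Pearson correlation maps with the +-0.4 threshold,
  and colocalization versus curvature;
* Kelvin-Voigt creep analysis of constant-force pulling data, with the
  unit conventions (kcal/mol/Angstrom to pN, Angstrom^2 areas, GPa
  stresses) and the equivalent-chain reduction of multi-chain coordinates;
* non-parametric cohort statistics (Mann-Whitney for two groups,
  Kruskal-Wallis for three or more) and a reproducible pipeline driver.

Because raw microscopy and molecular-dynamics trajectories are not
desk-reproducible, every estimator is paired with a synthetic generator
that produces images, movies and traces with known ground truth. The
generators are first-class, tested code: the package's claims are
validated by round-tripping generator parameters through the estimators.

## Geometry: curvature of the equatorial contour

A nuclear contour is a closed planar polygon in micrometres
([`NuclearContour`]). `splineCurvature()` interpolates it with a periodic
cubic spline under chord-length parameterization and evaluates

$$\kappa(s) = \frac{\dot x \, \ddot y - \dot y \, \ddot x}
                   {(\dot x^2 + \dot y^2)^{3/2}}$$

at points equally spaced in arc length. The expression is invariant to the
parameterization, so derivatives are taken with respect to the chord
parameter directly. Signs are positive where a counterclockwise boundary
bulges outward; histograms use magnitudes. The curvature radius
`rEq = 1/kappa` is capped at 200 um (a 0.005 1/um curvature floor) to
avoid division blow-ups on locally straight stretches; the floor is a
package convention, chosen because nuclear contours at this magnification
rarely support meaningful radii beyond tens of micrometres.

Automatically traced boundaries are pixel staircases; `extractContour()`
therefore smooths the trace with a short circular moving average and
subsamples it before any curvature computation. A manually drawn polygon
ROI always takes precedence over automatic thresholding (Otsu on the
lightly smoothed plane), mirroring the original manual workflow.

```{r curvature-example}
prof <- splineCurvature(ellipseContour(2, 1, n = 512), nSamples = 400)
range(curvature(prof)$kappa)   # b/a^2 = 0.25 to a/b^2 = 2 (1/um)
```

The nucleus as a whole is modelled as an ellipsoid with equatorial
semiaxes `a >= b` and axial semiaxis `c`, measured from the thresholded
orthogonal projections of a z-stack. The semiaxes come from second-order
moments of the projection masks (for a filled ellipse the variance along a
principal axis is semiaxis^2/4) with Sheppard's correction for pixel
discretization. A raw z-extent would be quantized to the 0.5-um z-step of
a confocal stack; the moment estimate is sub-voxel and is used for all
three axes for consistency.

At an equatorial point the two normal-section curvatures are the planar
curvature of the `(a, b)` equatorial ellipse (`Keq`) and the curvature of
the meridian section, `Km = r(theta)/c^2`, where `r(theta)` is the
centre-to-point equatorial radius. Between the tips of the two equatorial
axes, `Km` varies by a factor `a/b` and `Keq` by `(a/b)^3` — identically
the cube, which is why a modest equatorial elongation (`a/b` of 1.3 versus
1.8) translates into equatorial-curvature variation factors of about 2
versus 6.

## Tracking and envelope crossings

Spot detection is Laplacian-of-Gaussian: smoothing at
`sigma = diameter / (2 sqrt 2)` pixels, a Laplacian response, local maxima
above `k` MADs of the response (k = 6 by default) and sub-pixel centroid
refinement. Linking is greedy nearest-neighbour with a hard `r_max` of
1 um per 10-ms step and no gap closing; on small instances the greedy
assignment is validated in the test suite against a brute-force optimal
matcher.

The crossing analysis considers steps whose start lies outside the nucleus
within a 5-pixel band of the envelope. In the simulation model, a molecule
proposing a step into the nucleus translocates with probability
`pCross(rEq)` evaluated at the nearest contour sample; otherwise it is
stopped at the envelope — its realized position is the nearest boundary
point, which is how a molecule turned back at a pore presents in data.
The classifier mirrors this: a band-origin step ending inside is a
crossing, one ending on the contour (within `touchTol`) is a rejected
approach, and band steps that never head inward are not approaches. With
this convention the crossing-fraction estimator is an unbiased estimator
of the translocation probability, which the tests verify.

The crossing fraction is binned over `rEq` in equal-count bins (default
8: per-bin counts stay balanced and the weighted least-squares t-test on
the slope keeps its nominal size, which 3-4 bins do not) and fitted with
weights `1/SE^2`. Both the t-test p-value and a label-permutation p-value
are reported.

```{r crossing-example}
ct <- ellipseContour(8, 5, n = 256, center = c(10, 10))
ae <- makeApproachEvents(ct, nEvents = 2000, pCross = 0.5, seed = 1)
ev <- classifyCrossings(ae$tracks, ae$profile)
round(100 * mean(ev$crossed), 1)  # ~50% by construction
```

## Intensity morphometry

All intensity metrics are invariant to multiplicative rescaling. The
coefficient of variation uses the sample (n-1) standard deviation. The
edge/interior ratio beta uses a 5-pixel edge band (0.725 um at 145 nm/px)
and the interior eroded by the same band; both the pixel and micrometre
interpretations of the band width are configurable because the two
conventions differ slightly at other magnifications.

The lamin rim profile is sampled along the nuclear major axis, positions
normalized to the diameter and intensities to their maximum. The
two-segment fit minimizes the total residual sum of squares of two
least-squares lines over an exhaustive breakpoint grid; the edge slope
alpha is the first segment's slope and the lamina occupancy is 100 times
the breakpoint. On an exactly piecewise-linear profile the kink sample
lies on both lines, so near-ties are resolved toward the rightmost
candidate (the kink closes the edge segment). Numerically straight
profiles, where no breakpoint improves the single-line fit by more than
1%, are flagged degenerate and the whole-profile slope is reported.
Whether the published occupancy percentages derive from a breakpoint or
from an intensity threshold is not documented; the breakpoint definition
is implemented and exposed.

Actin directionality uses the structure tensor with derivative-of-Gaussian
gradient filters — unlike plain finite differences their frequency
response is isotropic, so the orientation of a pure oriented pattern is
estimated without angular bias. Per-pixel orientations are binned at 1
degree from -90 to +90 (the two boundary bins alias the same orientation)
weighted by the tensor anisotropy, which suppresses fiber crossings.
Cohort histograms are aligned at their peak and Gaussian-fitted. Dense
fiber meshworks narrow the fitted spread slightly (crossing suppression
removes outlier-angle fibers preferentially), so the spread-recovery
checks run on sparse fiber images while goodness-of-fit checks use dense
ones.

Correlation maps are per-pixel Pearson coefficients over a sliding window
(default 5 px; windows are truncated at the image border, and constant
windows are masked rather than propagated as NaN). Thresholding removes
the closed interval [-0.4, +0.4], endpoints included. Region percentages
are computed over surviving positively-correlating pixels and sum to 100
across the edge band and the interior.

## Kelvin-Voigt creep analysis

A constant pulling force `F` over the cross-sectional area `A` of a single
alpha-helix gives the instantaneous stress `sigma0 = F/A`; with F = 140 pN
(2 kcal/mol/Angstrom) and A = 78.54 Angstrom^2 that is 0.17825 GPa. The
printed 78.54 Angstrom^2 corresponds to `pi * (5 Angstrom)^2`, i.e. it
treats the quoted 5 Angstrom as a radius even though it is described as a
diameter (`pi d^2 / 4` would give 19.63); the printed area wins here and
`circleArea()` documents the convention.

The creep response of a Kelvin-Voigt solid is
$$\varepsilon(t) = \frac{\sigma_0}{E}\left(1 - e^{-E t/\eta}\right),$$
fitted by Levenberg-Marquardt least squares with `E` initialized from the
plateau (`sigma0 / final strain`), `eta` from the initial slope
(`d eps/dt(0) = sigma0/eta`), and positivity bounds. The first sample is
subtracted so curves start at zero strain. Time units ("s" or "ns") are
carried explicitly and the fitted viscosity is reported in matching units;
the fit itself is invariant to the unit choice. Curves spanning fewer than
two retardation times `eta/E` trigger a plateau warning. When several
equilibration replicas are analyzed, strains are averaged before fitting.

```{r creep-example}
cc <- makeCreepCurve(E = 0.23, eta = 0.12, forcePN = 140, areaA2 = 78.54)
fitKelvinVoigt(cc)
```

Multi-chain pulling geometries are reduced to an equivalent chain by
averaging the fixed-terminal and steered-terminal coordinates over chains
(`equivalentChain()`, with `chainTerminalsFromPDB()` reading the terminal
C-alpha atoms, residues 79 and 222 by default, from a PDB file).

## The synthetic cohort and what it does (not) show

`simulateCohort()` renders, per cell, a lamin equatorial plane and a
chromatin plane and runs the full measurement chain on the images. The
per-condition defaults are the study conditions themselves: semiaxis
ratios b/c of 3, 2 and 1 for Flat, Flat+CD and Nichoid, with the axial
semiaxis doubling from Flat to Nichoid and equatorial elongations a/b of
1.3 and 1.8; lamin edge slopes of -0.183 +/- 0.089, -0.386 +/- 0.214 and
-0.765 +/- 0.356 (per-cell slopes are drawn from these distributions);
lamina occupancies of 64% and 21% with the treated condition set between
them at 45% (no published value exists for it); and chromatin clustering
and edge-texture CV chosen so the homogeneity orderings match the
biology (chromatin more homogeneous, lamin edge more textured in the
Nichoid). Where the study reports no number — interior lamin levels, the
rim brightening used for beta, blob counts, noise levels — values were
fixed once at what fluorescence images of this kind plausibly show, and
are documented in `defaultCohortParams()`.

The generator emulates piecewise-linear rim profiles, blob-textured
chromatin, Gaussian-spot molecules and additive Gaussian read noise with
optional Poisson shot noise and a Gaussian PSF. It does not emulate
nucleoli (a manual avoidance mask is accepted instead), illumination
fields, aberrations, photobleaching or dye photophysics. Green tests
therefore demonstrate that the estimators recover known ground truth and
reproduce the published orderings under these idealized conditions; they
do not certify performance on real microscopy.

Two interpretation choices deserve explicit mention. First, the
crossing-fraction denominator: published counts are per-jump, and
approaches are defined per-jump here too (re-entries of one track count
separately). Second, the beta ordering between conditions at the
equatorial plane is not printed in the source study (both conditions show
beta > 1); the synthetic cohort gives the rounder nucleus the stronger
equatorial rim, so beta(Nichoid) > beta(Flat) is the ordering the cohort
reproduces.

## Numerical conventions and problem sizes

Pixel centres sit at 0-based integer multiples of the pixel size (default
0.145 um); contours are converted to micrometres before any geometry.
Default problem sizes keep the full test suite at a few minutes: cohorts
of 50 cells per condition on ~5-um nuclei, 100-run null calibrations with
600 approaches each, 720-1440-vertex analytic contours for oracle
comparisons, and 1000-sample creep curves. The statistics follow the
source conventions: raw two-sided non-parametric tests (Mann-Whitney for
two groups, Kruskal-Wallis for more), significance stars at 0.05, 0.01,
0.001 and 0.0001, and no multiple-testing correction by default
(Benjamini-Hochberg is available as an option). The Young's modulus used
for creep round-trips is the Results-section value of about 0.23 GPa; the
0.6 GPa quoted elsewhere in the source's discussion is inconsistent with
it and is not used.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates every input and recomputes the
desk-scale quantities (recovered E and eta, the Flat b/c ratio, the
curvature-independent crossing percentage, beta on a uniform plane, and
the two lamina occupancies); see the README for the exact invocation.
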