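---
title: "Quantifying shoot apical meristem shape and reporter expression"
author: "apexquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shoot apical meristem shape and reporter expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apexquant)
```

## The measurement problem

During floral transition the Arabidopsis shoot apical meristem (SAM)
"domes": it grows in height and width and its internal zonation — the
CLV3-marked central zone (CZ), the WUS-marked organising centre (OC) and
the peripheral zone (PZ) — reorganises. Quantifying this from confocal
z-stacks poses three distinct problems, each with its own pipeline in
this package:

1. **Reporter concentration at the shoot apex.** Diffuse translational
   fusions (SOC1:GFP-like, AP2:VENUS-like) must be quantified only
   inside the meristem proper, excluding organ primordia and
   out-of-tissue background. The package masks the stack with a 3D
   paraboloid fitted to the meristem's own curvature and reports total
   intensity divided by total volume in the apical region.
2. **Expression-domain geometry.** Nuclear-localised transcriptional
   reporters (WUS::3xVENUS-NLS, CLV3::mCHERRY-NLS) form compact domains
   whose size is summarised by an ellipse fitted to the half-maximum
   isocline of orthogonal sum projections.
3. **Morphometrics.** SAM height, width and area come from landmark
   placements on orthogonal views and from externally segmented
   per-cell area tables.

A statistics layer reproduces the reporting conventions used with such
data: two-sided Mann-Whitney-Wilcoxon tests between genotypes per
timepoint, one-way ANOVA with Tukey post-hoc comparisons rendered as
compact letter displays, per-experiment normalisation by the reference
genotype's median, and median fold changes.

## Conventions

Stacks are `(z, y, x)` arrays; slice `z = 1` is the top (apex-side)
slice and z increases into the tissue. Coordinates are voxel-centred:
index `i` (1-based) on an axis of spacing `s` sits at `(i - 1) * s`
micrometres. All physical quantities are in micrometres (µm, µm², µm³);
intensities are arbitrary units.

## The paraboloid mask pipeline

Confocal stacks are anisotropic (typically 0.2 µm laterally, 0.4 µm
axially), so `resampleIsotropic()` first increases the slice count by
cubic interpolation along z until the axial spacing equals the lateral
pixel size. The kernel is the Catmull-Rom (Keys, a = −0.5) form of the
bicubic kernel applied per `(y, x)` column. Boundary handling and
overshoot are not dictated by the kernel itself, so the package fixes
them: edge slices are clamped (replicated), and interpolation overshoot
below zero is clipped to 0. Edge clamping means polynomial reproduction
holds away from the first and last source interval; constants are exact
everywhere, linear and quadratic profiles are exact in the interior, and
cubic profiles are reproduced to third-order accuracy (an exactly-cubic
test signal is not reproduced to machine precision — that would require
a different kernel family than the one chosen here).

The mask is built semi-automatically, mirroring a protocol in which the
outline is drawn by hand:

* `sumProjection()` produces the two orthogonal side views (xz and yz)
  of the cell-wall channel. The out-of-plane lateral axis is collapsed
  by summing over an interval of slices containing the apex (default:
  the central half of that axis). Collapsing the *lateral* axis — rather
  than z — is the reading under which a single-slice interval returns
  exactly that slice's plane, and it is the one that produces a side
  view an outline can be drawn on.
* Outline points (here: supplied as coordinates, e.g. exported from an
  annotation tool or generated synthetically — interactive drawing is
  out of scope) are fitted by `fitParabola()`. For each candidate
  orientation θ the points are rotated into the candidate frame and
  `w = w0 + a (u − u0)²` is fitted by least squares; the θ minimising
  the residual sum of squares wins. The orientation search runs on a
  coarse 1° grid over ±20° followed by golden-section refinement to
  ~0.05°. (A description of this step as minimising "the R² value"
  should be read as minimising the residual — minimising the
  coefficient of determination itself would select the *worst*
  orientation.)
* `buildParaboloid()` assembles
  `z = z0 + (x − x0)²/c1² + (y − y0)²/c2²` in the tilt-rotated frame,
  with `c1² = 1/a_xz`, `c2² = 1/a_yz` so the surface matches each 2D
  fit's quadratic term in its own plane, and `z0` the mean of the two
  apex depths. When the lateral view is truncated (stacks often do not
  cover the meristem's full y extent) the xz curvature is reused
  (`c2² = c1²`). Tilt is a single rotation about the y axis — the
  dominant tilt direction in mounted apices; applying it in one plane
  keeps the geometry invertible and matches the synthetic generator.
* `inflateCurvature()` narrows the paraboloid (`a' = a/α`, 0 < α < 1,
  α conventionally the image resolution in µm) to keep boundary and
  primordium signal out; `applyMask()` zeroes the channel outside.
  A voxel is interior iff its *centre* satisfies the inequality in the
  rotated frame — the simplest deterministic rasterisation rule.

`upperRegion()` then restricts to the region between the paraboloid and
a transversal plane at depth 20 or 50 µm below the apex. The plane is
cut perpendicular to the *paraboloid axis* (not the image z axis): the
depth limit is part of the meristem's own geometry, so it should tilt
with it. `concentration()` reports total intensity divided by total
volume; the conventional display value divides by a further 1000.
For diffuse GFP-fusion profiles a Gaussian filter (σ = 2.5 px) is
applied inside the paraboloid first; smoothing is opt-in per profile and
recorded in the result. The in-region filter is renormalised
(mask-weighted, `conv(I·M)/conv(M)`), so voxels near the mask boundary
are not diluted by the zeroed exterior — plain convolution would bleed
the hard-masked zeros inward and bias edge voxels low.

## The domain-geometry pipeline

`cropSubstack()` restricts to the user-chosen rectangle containing the
SAM (excluding primordium signal), `orthogonalProjections()` sums the
whole sub-stack along y and along x, and `isoclineEllipse()` extracts
the level-set contour at 50% of the projection maximum and fits an
ellipse. Numerical choices:

* the projection is smoothed with a σ = 1 px Gaussian before the
  maximum is taken (and the contour extracted from the same smoothed
  image) — the raw maximum of a sum projection is noise-dominated;
* the contour comes from marching squares with linear (sub-pixel)
  interpolation (`grDevices::contourLines`); the contour enclosing the
  maximum is used;
* the ellipse is fitted by a direct least-squares conic fit with an
  ellipse constraint, falling back to the second-moment (equivalent)
  ellipse when fewer than 6 contour points are available;
* a contour touching the crop border is an error, never a silent fit;
* "maximal expression" is per projection, not per stack — each side
  view is thresholded against its own maximum;
* the threshold is relative, so the result is invariant to global
  intensity scaling.

Reported heights and widths are **full** axis lengths (2 × semi-axis):
the peripheral-zone formula `(W − w_oc)/2` is only geometrically
meaningful with full widths. The axis closer to the image vertical is
the height. The two side views are combined by averaging (both per-view
values are retained); for the half-maximum contour of a 3D Gaussian
domain with lateral sd σ the recovered full width converges to
`2σ√(2 ln 2)` as pixel size shrinks.

`peripheryMetrics()` derives PZ width `(W − w_oc)/2` and the PZ/OC
ratio, taking the meristem width W from the morphometric measurement
(not re-deriving it from projections).

## Morphometrics

`measureView()` enforces the landmark criteria — width between the two
endpoints at the most apically visible primordium, height perpendicular
to the width segment — making the measurement invariant to how the
sample lies in the image. Landmarks are explicit inputs: the protocol
step is manual, and taking placed points keeps it reproducible.
`mergeViews()` averages the two orthogonal views as technical
replicates. `shapeParabola()` renders a record as the canonical
downward parabola `y = H(1 − (2x/W)²)` through `(0, H)` and `(±W/2, 0)`,
colour-keyed by primordium identity; identity (vegetative / cauline /
floral) is an annotation, never computed. `meristemArea()` sums member
cells of an ingested segmentation table — surface extraction and
curvature-based membership belong to the external segmentation tool.
The peak timepoint per genotype is the argmax of per-timepoint median
height, ties broken toward the earlier timepoint.

## Statistics

`compareGenotypes()` uses the exact two-sided rank-sum distribution for
groups of ≤ 8 without ties and the tie-corrected normal approximation
otherwise. `compareTimepoints()` runs classic (equal-variance) one-way
ANOVA — legends describing such analyses rarely specify Welch, and the
classic form is the default reading — followed by Tukey HSD; the
compact letter display is computed by insert-and-absorb over the Tukey
p matrix and its defining invariants (shared letter ⇔ p ≥ α) are
asserted on every output. α defaults to 0.05 everywhere and is
configurable. No multiplicity correction is applied across the
Mann-Whitney series, matching the reporting convention being
reproduced.

## What the synthetic generator does and does not emulate

`makeDomeStack()` builds a tilted paraboloid surface, a Gaussian
cell-wall shell of constant thickness around it, and reporter channels
(uniform-interior, depth-graded, or 3D-Gaussian nuclear domains)
restricted to the tissue interior, then applies Poisson shot noise
(gain g) plus additive Gaussian read noise with clipping at 0 — the
standard confocal approximation. The default grid is 128 × 128 × 96 at
0.2/0.2/0.4 µm, mirroring routine acquisition anisotropy. Every
manifest records the full ground truth (apex, curvatures, tilt,
channel parameters, interior voxel count, morphometric landmarks for
untilted domes).

Not emulated: cell packing, the optical point-spread function,
depth-dependent attenuation, photobleaching, and the
orientation-dependent brightness of real cell-wall stain. Two
consequences matter for interpreting green tests. First, a
constant-thickness shell projects to a flat-topped profile, so apex
localisation from projections is only defined up to that plateau —
tests therefore check the projection *centroid*, and on real data the
apex is set by the user-drawn outline anyway. Second, with a zero
background the clip-at-0 step makes exterior noise voxels biased upward
by construction; unbiasedness of the concentration estimator holds
where it is used, inside the tissue, far from the clip. Passing tests
demonstrate correctness of the geometry, the masking, the estimators
and the statistics on ideal dome-shaped tissue; they do not certify
robustness to segmentation-grade image artefacts.

`makeTimecourse()` draws lognormal cohorts around design medians. The
default design anchors the wild-type trajectory to a doubling of median
height (45 → 90 µm) and a 1.5-fold width increase (70 → 105 µm) over
the timecourse, with the mutant genotype plateauing to 50% smaller
height and 25% smaller width at the wild-type peak — the headline
morphometric contrasts this kind of study reports. Absolute sizes are
in the range typical of Arabidopsis apices. Dispersion defaults to
lognormal sdlog 0.10 (≈ 10% CV), a deliberately clean cohort: the
generator validates the analysis layer, not biological variability.
Cross-genotype summary checks pool six simulated experiments of n = 8
per genotype × timepoint, the pooled multi-experiment design such
comparisons use in practice; significance tests run within a single
experiment at n = 8 per group.

## Problem sizes and determinism

The validation suite runs on grids of 64³–96 × 128 × 128 voxels, 20
seeded dome replicates for mask recovery, 50 noise replicates for the
concentration estimator, and 2000 null replicates for the type-I-rate
check — sizes at which every Monte-Carlo margin (3 standard errors;
binomial width of the rejection-rate band) is comfortably resolved.
All generators are pure functions of (spec, seed); `runPipeline()`
re-run with the same configuration and seed produces byte-identical
tables, and its manifest (configuration hash plus every output path) is
sufficient to reproduce a run.

## Known limitations

* The paraboloid is a single global surface: per-primordium masking,
  saddle geometries, and spline surfaces are out of scope.
* The transversal-plane and single-axis-tilt conventions are stated
  choices; strongly doubly-tilted mounts would need a two-angle
  extension.
* TIFF voxel metadata is written as a JSON sidecar (`<path>.json`);
  ImageJ-style description tags and resolution tags are parsed on
  reading, but files from other writers may need an explicit override.
* Domain ellipses assume a single compact domain per projection; ring
  or split domains yield a border/containment error rather than a fit.
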