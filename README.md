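# apexquant

Quantitative confocal image analysis of the *Arabidopsis* shoot apical
meristem (SAM) during floral transition: meristem shape, fluorescent
reporter concentration at the shoot apex, and the geometry of
stem-cell-regulator expression domains.

## Who this is for and what it computes

When plants switch to flowering, the SAM "domes": its height roughly
doubles while its width increases about 1.5-fold, and the CLV3-marked
central zone, WUS-marked organising centre (OC) and peripheral zone (PZ)
change size alongside. Measuring this from multi-channel confocal
z-stacks needs three pipelines, all implemented here for anyone
quantifying meristem (or meristem-like) tissue:

1. **Reporter concentration in a paraboloid mask.** The stack is
   resampled to isotropic voxels by cubic interpolation along z; a
   paraboloid

   *z = z₀ + (x − x₀)²/c₁² + (y − y₀)²/c₂²*

   is fitted to the meristem outline via parabola fits in the two
   orthogonal side views (with an orientation search handling tilted
   mounts, and c₂² = c₁² as the fallback when the lateral view is
   truncated); the curvature is inflated (*a′ = a/α*, α < 1) to exclude
   boundary signal; voxels outside are zeroed; and the *concentration
   of fluorescence intensity* — total intensity / total volume — is
   measured between the paraboloid and a transversal plane 20 or 50 µm
   below the apex (values reported ÷ 1000).
2. **Expression-domain geometry.** After cropping to the SAM, sum
   projections in both side views are thresholded at 50% of their
   maximum; an ellipse fitted to the sub-pixel isocline yields domain
   height and width (full axes, µm). PZ width is (W − w\_oc)/2, with W
   the meristem width and w\_oc the WUS-domain (OC) width.
3. **Morphometrics + statistics.** Landmark-based height/width per
   orthogonal view (averaged as technical replicates), meristem area as
   the sum of segmented cell areas, canonical shape parabolas
   *y = H(1 − (2x/W)²)*, and the reporting layer: two-sided
   Mann-Whitney-Wilcoxon per timepoint, one-way ANOVA + Tukey compact
   letter displays across timepoints, per-experiment normalisation by
   the reference genotype's median, and median fold changes.

A synthetic-stack generator (`makeDomeStack()`, `makeTimecourse()`)
produces domed tissue, cell-wall shells, diffuse and nuclear reporter
channels with Poisson + Gaussian noise, and cohort tables — each with a
complete ground-truth manifest, so every stage is testable without
microscope data.

## Worked example

Simulate a tilted dome with a noisy uniform reporter (true value
100 a.u. per 0.2³ µm³ voxel ⇒ true concentration 12 500 a.u./µm³,
reported 12.5), then run the mask pipeline:

```r
library(apexquant)

dome <- domeSpec(apexUm = c(12.8, 12.8, 4), curvatures = c(0.05, 0.06),
                 tiltDeg = 8)
gen <- makeDomeStack(dome,
  list(reporterSpec("gfp", value = 100, poissonGain = 1, readSd = 2)),
  dim = c(96, 128, 128), voxelSizes = c(0.2, 0.4), seed = 42)

iso <- resampleIsotropic(gen$stack)
iso
#> IsotropicStack: 2 channel(s) [wall, gfp], grid 191 x 128 x 128 (z,y,x)
#>   voxel size: 0.2 (xy) x 0.2 (z) um
#>   provenance: resampled z 0.4 -> 0.2 um (Catmull-Rom cubic, edge-clamped)

pts_xz <- makeOutlinePoints(c(12.8, 4), 0.05, tiltDeg = 8, n = 60,
                            noiseSd = 0.1, seed = 1)
pts_yz <- makeOutlinePoints(c(12.8, 4), 0.06, n = 60, noiseSd = 0.1,
                            seed = 2)
pb <- buildParaboloid(fitParabola(pts_xz), fitParabola(pts_yz))
pb
#> Paraboloid3D: apex (12.78, 12.76, 4.01) um, c1^2 = 19.99, c2^2 = 16.71 um^2
#>   tilt = 7.91 deg; lateral view complete

quantifyReporter(iso, pb, "gfp", depthUm = 20, alpha = 0.5)
#> FluorMeasure [gfp, depth 20 um]: total 6.998e+07 a.u. / 5598 um^3
#>   concentration 12501 a.u./um^3 (reported 12.501)
```

The fitted paraboloid recovers the configured geometry (apex within a
hundredth of a voxel, c₁² = 1/0.05 = 20 µm², tilt 8°), and the measured
concentration lands on the true 12 500 a.u./µm³ to within shot noise.
`runPipeline()` chains these stages (plus the cohort statistics) from a
single declarative config and writes CSVs with a manifest;
`isoclineEllipse()` / `peripheryMetrics()` cover the domain-geometry
side. See the vignette in `vignettes/` for the full model description.

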