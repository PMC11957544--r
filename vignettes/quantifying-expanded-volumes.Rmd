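---
title: "Methods: quantifying expanded whole-organism volumes"
author: "voxcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying expanded whole-organism volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxcensus)
```

# Scope and data model

voxcensus quantifies 3D fluorescence volumes of expanded, cleared
whole-organism specimens imaged by light-sheet microscopy: counting nuclei
and neurons, measuring whole-body morphometry, and tracing body-wall muscle
fibers. All data live in a `VoxelGrid`: a `(z, y, x)`-indexed scalar array
with per-axis voxel spacing in micrometres and a linear expansion factor.
Voxel centres sit at `(i - 1) * spacing`, and all physical boxes are
half-open, which keeps region censuses free of off-by-one double counting.

Physical expansion trades field of view for resolution: a specimen expanded
`E`-fold and imaged at optical resolution `r` is effectively resolved at
`r / E` in biological units (`effectiveResolution()`). With the 1x air
objective used for cellular imaging (2 x 2 x 5 um optics) and 4x isotropic
expansion this gives 0.5 x 0.5 x 1.25 um. Because published figures mix
expanded and biological scales, every measurement here is reported in
expanded-sample micrometres unless `scale = "biological"` is requested
explicitly; the expansion factor then divides lengths once, areas twice and
volumes three times.

# Nucleus and neuron counting

The counting chain (`countNuclei()`) is

1. Gaussian smoothing (or Perona-Malik diffusion) — shot-noise suppression;
2. multiscale Hessian "ball" enhancement (`ballness()`);
3. thresholding of the enhancement response;
4. removal of sub-nuclear specks (`removeSmallSpots()`);
5. marker-based watershed (`watershedLabel()`);
6. a label census (`countLabels()`), optionally split by anatomical region.

## Hessian ball and rod measures

The Hessian at scale `sigma` (voxels) is built from sampled Gaussian
derivative filters and normalised by `sigma^2` (the gamma = 2 convention),
so that response maxima across scales track structure size. Eigenvalues are
sorted by absolute value, `|l1| <= |l2| <= |l3|`.

The commercial ball/rod recognition operators this mirrors are
undocumented, so the package uses the nearest published formulations and
states them exactly:

* **ballness** `B = |l1| * (|l1| / |l3|)` where all three eigenvalues carry
  the polarity-consistent sign (all negative for bright nuclei), else 0.
  `|l1|` — the weakest principal curvature — is large only when intensity
  curves downward in *every* direction, and the sphericity factor
  `|l1|/|l3|` suppresses tubes and plates. The multiscale response is the
  voxelwise maximum over the scale list, normalised to [0, 1] by its global
  maximum, making it invariant under affine intensity rescaling. For a
  Gaussian blob of sd `s`, the continuous theory puts the argmax scale at
  `s * sqrt(2/3) ~ 0.82 s`, within one unit scale step of `s` over the
  relevant range — the property the scale-selection test checks for
  `s = 2, 3, 4` against the 1..6 scale list.
* **rodness** is classical Frangi vesselness with `alpha = beta = 0.5` and
  the noise scale `c` set per scale to half the maximal Hessian Frobenius
  norm; the eigenvector of `l1` provides the tube axis. It is naturally in
  [0, 1] and is not renormalised.

Scale presets mirror the published parameter sets, interpreted in voxels of
the processed grid: head-region nuclei 1-6 step 1, other body regions 1-3,
neuron markers 2-5, fibers a single scale 1.

## Thresholding

Automatic thresholding uses Otsu's criterion on a 256-bin histogram and
always logs the chosen value — the reproducible counterpart of the
interactive-threshold checkpoint in GUI workflows. For the *enhancement
response*, however, `countNuclei()` defaults to a fixed fraction (0.05) of
the response maximum instead: the response histogram is dominated by the
strongest isolated nuclei, and Otsu's valley then sits high enough to drop
nuclei whose ballness is weakened by a touching neighbour. The fraction is
a visible parameter, logged with every run.

## Watershed and markers

Instances are separated by priority-flood watershed. The default landscape
is the negated Euclidean distance transform of the mask (exact anisotropic
EDT via the Felzenszwalb lower-envelope method); `countNuclei()` instead
floods the negated smoothed intensity, so touching nuclei split at the
intensity valley between their peaks — the behaviour of marker-based
watershed on real PI data. Markers come from regional minima after h-minima
suppression (greyscale reconstruction), with `h` defaulting to 1 voxel of
distance for EDT landscapes and to 10% of the dynamic range for intensity
landscapes. Flooding resolves equal-priority ties first-queued-first-served,
which makes labelling deterministic; the suite checks exact agreement with
an independent brute-force priority flood on randomised small instances.
Connectivity defaults are 26 for components and spot removal, 6 for hole
filling (the conservative hole definition) and 6 for flooding.

# Morphometry

`bodyMask()` reduces a nuclei-stained volume to a single connected body
mask: optional budget-driven resampling (isotropic in voxel counts, so
aspect ratios survive), strong diffusion, thresholding, interior hole
filling, and morphological closing with a ball (default radius 5 voxels).
Closing stands in for the ambient-occlusion smoothing of the original
workflow: both suppress surface pits, and closing is deterministic and
cheap. `measureBody()` reports:

* length/width/depth — extents along the principal axes of the mask's
  voxel covariance (plus one voxel pitch for the half-open support);
  straight-line extents, not curved centrelines, and labelled as such;
* volume — voxel count times voxel volume;
* surface area — the area of the 0.5-level isosurface of the Gaussian-
  smoothed mask, extracted by marching tetrahedra (six tetrahedra per
  cube). Counting voxel faces would overestimate a sphere's area by ~50%;
  meshing the *raw* binary mask still overestimates by ~28%. Smoothing
  before meshing removes the staircase, at the price of rounding sharp
  edges. The default `smooth_sigma = 0.7` voxels balances the two regimes:
  digital spheres of radius 10-40 come out within ~1% of `4 pi r^2` and
  cubes of side >= 20 within ~2.6% of `6 a^2` on the dimensionless index
  below. Surface-accurate measurement of bodies thinner than ~10 voxels is
  outside the method's reliable range.

The dimensionless shape index `sqrt(SA) / cbrt(V)` is scale- and
expansion-invariant, minimised by the sphere at 2.199 (`sqrt(6) = 2.449`
for a cube); its constancy across animal sizes is the morphometric
signature of isometric growth.

`brainLobeAngle()` needs an operational definition the source material
never gives: here it is the angle between the first principal axes of the
two lobe point clouds after projection onto the coronal plane, the plane
orthogonal to the pooled cloud's smallest-variance axis. Collinear clouds
are rejected rather than silently projected.

# Fiber tracing

`cylinderCorrelate()` computes zero-normalised cross-correlation between
the volume and a solid-cylinder template swept over a quasi-uniform
orientation sample of the hemisphere (`makeOrientationSet()`; rings spaced
by the angular step, worst-case covering radius ~0.71 steps, antipodes
excluded). The template interior (anti-aliased over one voxel) has value 1
out to the outer radius; the annulus to the mask radius is the local
background reference; nothing outside the mask radius enters the support.
With the published anterior-pole parameters — length 18, outer radius 2.8,
mask radius 3, angular sampling 5 — the annulus is 0.2 voxels wide; the
package reads "angular sampling 5" as 5 degrees, the unit of the original
module, and keeps the key unit-explicit. "Inner diameter" appears in the
source prose without a value, so templates are solid. Voxels whose
neighbourhood has no intensity variance get correlation 0 by convention,
and an optional intensity floor skips empty background in sparse volumes
without changing results where fibers live.

`traceCorrelationLines()` extracts polylines by ridge following: local
correlation maxima above the seed threshold start traces in descending
order; steps of one voxel follow the locally best orientation, re-evaluated
each step with the per-step turn capped at 30 degrees; a trace ends when
the interpolated correlation falls below the continue threshold (default
0.6 of the seed threshold) or claimed territory is entered. Claiming a tube
of the template's outer radius around each accepted trace resolves
crossings deterministically in favour of the stronger fiber — a
reproducibility-over-recall choice; fibers interrupted by a stronger
crossing fiber may fragment, which slightly inflates trace counts but
preserves recovery.

Orientation classes use the body frame (rows AP, ML, DV): fibers within 30
degrees of DV are dorsoventral; the rest are binned by the in-plane angle
to AP — longitudinal below 30, diagonal to 60, circular beyond. The 30/60
boundaries are this package's own; the source names the classes but never
the angles. Classification is invariant under axis sign flips.

# The phantom generator

Every stage is validated on seeded synthetic volumes with exact truth:

* **nuclei** — Gaussian-profile spheres (profile sd = radius/2), radii 3-5
  um at 1 um isotropic spacing, SNR 10 by default; a designated fraction of
  nuclei is placed as touching pairs at 1.5 radii centre distance, the case
  watershed must split. SNR is defined as (object peak - background mean) /
  background sd, realised as Poisson shot noise plus Gaussian read noise.
* **fibers** — anti-aliased solid cylinders (radius 2, length 60 by
  default, SNR 5) at orientations drawn 5 degrees inside their class bins,
  with a minimum pairwise clearance of 8 um. The radial coverage ramp is
  rendered at `sqrt(r^2 - 1/12)` so the rendered mass tracks `pi r^2 L`;
  axis-aligned cylinders sitting exactly on the lattice remain the worst
  case (~2% mass excess) and the mass checks therefore use oblique axes.
* **bodies** — spheres, cubes and capsules with closed-form volume, area
  and length, rendered as anti-aliased coverage or as a dense nuclei fill
  (a jittered 3 um lattice of dots whose centres stay at least one nucleus
  radius inside the surface, emulating near space-filling PI staining).
* **allometry tables** — per-animal (cells, neurons, brain neurons) rows
  following a one- or two-segment linear law, continuous at the breakpoint,
  with multiplicative noise.

What the phantoms do **not** emulate: optical anisotropy and the axial PSF,
expansion distortion, staining heterogeneity, autofluorescence gradients,
and densely packed tissue where nuclei share boundaries with many
neighbours at once. Passing the phantom suite therefore demonstrates
algorithmic correctness under controlled conditions, not field performance
on arbitrary real volumes; the interactive checkpoints (thresholds, scale
ranges) exist precisely because real data need case-by-case adjustment.

# Allometry and statistics

`fitScaling()` fits neuron-versus-cell scaling with one segment (ordinary
least squares) or two. The two-segment model is a broken stick — continuous
at the breakpoint, `y ~ x + (x - c)+`, with `c` chosen by exhaustive grid
search over observed x. Continuity is imposed deliberately: counts cannot
jump as animal size crosses the breakpoint, and the residual surface of two
*unlinked* lines is nearly flat along the split, making the breakpoint
weakly identified. If the RSS improvement over one segment is below a
tolerance (default 0.10, above the ~4/n overfitting floor of the two extra
parameters), the fit reports "no breakpoint supported".

`compareGroups()` is the classical pooled-variance unpaired two-tailed
Student's t-test (not Welch, matching the source's naming), with the usual
significance stars and the zero-variance conventions (equal means: p = 1;
unequal: an error). `regenerationTimecourse()` summarises counts per day
and estimates the plateau onset as the first day from which the slope
fitted over all remaining days stays below 10% of the maximal per-day
slope; fitting over the tail rather than using single-day differences makes
the rule robust to sampling noise.

# Recipes, seeds and problem sizes

Pipelines can be described as YAML recipes: an input (a TIFF path or a
phantom description), an ordered stage list, and one global seed fanned out
per stage by a stable hash of the stage name. `validateRecipe()` checks
stage names and the data kind flowing between stages before anything runs;
`runRecipe()` logs every resolved parameter — including auto-chosen
thresholds, exactly once each — as line-delimited JSON, and repeated runs
are byte-identical. Bundled recipes under `inst/recipes/` carry the
published parameter sets (nuclei head/body, neurons, anterior fibers).

Validation problem sizes were chosen as the smallest volumes at the study's
object densities that leave the measured properties size-stable: nuclei
counting at 256^3 voxels with 500 nuclei (and 160^3 with 100), fiber
recovery at 160^3 with 50 fibers, noise-rejection at 48^3, analytic solids
at radii 10-40 voxels. The t-test null calibration uses 2000 replicates;
breakpoint recovery uses 100 animals spanning 1e5-1e6 cells so both
segments are populated.

# Known limitations

* Filament tracing is greedy; crossing fibers are resolved by claim order,
  not by global optimisation, and curved templates are not supported.
* Surface area degrades for bodies thinner than ~10 voxels and for sharp
  edges below ~20 voxels, as described above.
* Interpreting enhancement scales in voxels means resampling changes the
  effective physical scale range; resample first, then enhance.
* The "2D Hessian" slice-wise mode of the original workflow is not
  reproduced; the 3D operators cover its use cases here.
* Body length is a straight principal-axis extent; strongly bent specimens
  need a curved-centerline method this package does not provide.
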