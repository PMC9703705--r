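---
title: "Digital panicle traits from 3D point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital panicle traits from 3D point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panicle3d)
```

This vignette documents the models, conventions and numerical choices
behind panicle3d, in the spirit of a methods section: what each stage
computes, which knobs matter, and what the synthetic validation does
and does not establish about real data.

## Input model

The unit of analysis is a colored 3D point cloud — `N` points with XYZ
coordinates in reconstruction units and RGB intensities on the 0–255
scale — produced upstream by multi-view stereo reconstruction of a
panicle hanging in an imaging chamber. Reconstruction itself (feature
matching, dense depth, surface denoising) is out of scope: the cloud
is the input boundary. Two consequences follow. First, coordinates
have no intrinsic metric scale; an optional `units_per_cm` factor,
supplied by the user from a calibration object, converts areas to cm².
Second, point *color* is the only cue distinguishing panicle from
background, which is why segmentation is colorimetric.

Raw chamber images can be pre-masked with `mask_background()`: pixels
are converted to HSV (all three channels on 0–1, value =
max(R,G,B)/255) and retained iff hue, saturation and value fall inside
inclusive ranges, default h ∈ [0,1], s ∈ [0,1], v ∈ [0.15,1]. With
these defaults the mask only removes dark pixels — the black chamber —
which is the intent: the hue and saturation ranges are deliberately
all-pass, and bounds are inclusive so that the all-pass ranges really
do retain every pixel.

## Segmentation

Each point gets a greenness score, the Visible Atmospherically
Resistant Index VARI = (G − R)/(G + R − B). Vegetation scores clearly
positive; achromatic backgrounds score near 0. Points with a zero
denominator (G + R = B) are colorimetrically degenerate; they are
scored 0 and flagged, which makes them fail the strict `VARI > 0.1`
test — appropriate, since such points are never green.

The cloud is then partitioned by connected-component labeling: points
are binned on a voxel grid and components are taken over the
26-neighborhood of occupied voxels (delegated to `igraph`). The
cluster containing the most points with VARI strictly above 0.1 is the
panicle; ties break by larger cluster, then lowest label. The voxel
size is the resolution knob: too small fragments the panicle, too
large bridges it to clutter. The default, 2× the median
nearest-neighbour spacing of the cloud, adapts to reconstruction
density and sits comfortably between the intra-panicle point spacing
and the centimetre-scale gaps that separate the panicle from pots,
labels and walls. Grid connectivity is deterministic and near-linear;
its relation to metric distance is bracketed (and tested) both ways:
points closer than one voxel size always share a component, and linked
points are never farther than 2√3 voxel sizes.

## The panicle frame

All intrinsic traits are computed in a PCA frame: Z is the first
principal direction of the coordinates (the panicle's long axis), X
the second, Y = Z × X, origin at the cloud point with minimal
Z-projection (the panicle base). Two sign conventions make the frame a
*deterministic, rotation-equivariant* function of the geometry, which
in turn makes every trait rigid-motion invariant:

- the Z sign is disambiguated by an `up_hint` (the capture rig's
  vertical, default world +Z) — PCA eigenvectors are sign-ambiguous
  and "top of the panicle" is physical information the data cannot
  supply;
- the X sign is chosen so the third central moment of the X
  projections is non-negative. Without this, voxel counts computed in
  the frame would jitter under rigid motion of the input because
  binning is anchored at the minimum corner.

Degenerate inputs (fewer than 3 points, collinear or coincident
clouds, an eigenvalue ratio below 1e−10) raise geometry errors rather
than returning an arbitrary frame.

## Projected panicle area

The projection plane contains the Z-axis; its normal is the Y-axis
rotated by θ around Z. Sweeping θ in 5° steps over [0°, 180°) gives 36
projected areas (orthogonal projection is invariant under a half-turn,
so 180° suffices); their mean is the PPA used for normalization, and
the min, max and the areas perpendicular to the X and Y axes are
reported alongside.

The enclosed area of the projected 2D points is estimated three ways:

- **alpha shape** (default): Delaunay triangulation (own Rcpp
  implementation of Bowyer–Watson incremental insertion with
  walk-based point location), keeping triangles whose circumradius is
  at most alpha and summing their areas. A concave boundary is truer
  than a convex hull for a branched silhouette.
- **convex hull**: `chull` plus the shoelace formula; an upper bound
  on any sensible boundary area and a fast cross-check.
- **raster**: occupancy grid, morphologically closed and hole-filled
  (EBImage), counting cells. Insensitive to interior density but
  resolution-limited.

Numerical choices that matter:

- *Alpha default.* Orthogonal projection piles points up at the
  silhouette rim (the projected density of a curved surface diverges
  at grazing incidence), so the raw median nearest-neighbour spacing
  of projected points underestimates the typical spacing badly and
  would carve spurious holes in the interior. The default alpha is
  therefore 3× the uniform-equivalent spacing `sqrt(hull area / n)`
  of the *density-equalized* point set: the projection is first
  thinned to one representative original point per spacing-sized grid
  cell. On analytic fixtures this keeps every sweep area within a few
  tenths of a percent of the closed form while still following
  concavities at the branch scale.
- *Thinning cap.* If the thinned set still exceeds 10,000 points the
  cell size is re-derived from the hull area so the triangulation
  cost is bounded by silhouette area, not by sampling density.
- *Degenerate projections* (fewer than 3 distinct points) return area
  0 with a warning instead of erroring, so sweeps over pathological
  clouds stay total.
- Coordinates are normalized to a unit box before triangulation;
  areas are scaled back afterwards.

## Voxel count and color proportions

VC is the number of occupied voxels, binned in the PCA frame (for
rigid invariance) on a grid anchored at the minimum corner; the
default voxel size is again 2× the median nearest-neighbour spacing,
since the reconstruction density — not an absolute length — sets the
meaningful resolution. VC is monotone in resolution and bounded by N.

Color proportions come in two modes. The default `intensity` mode sums
channel intensities: green_prop = ΣG/(ΣR+ΣG), red_prop its complement
— a chlorophyll proxy robust to how individual points straddle the
green/red boundary. The `classify` mode counts green-dominant
(G > R) versus red-dominant points, which estimates the *fraction of
green points* directly and is the right scale for comparing against
the synthetic generator's programmed gradient. Both modes satisfy
green + red = 1 exactly; an all-blue/black cloud is an error, not a
silent 0/0.

## Slicing

The Z-extent of the cloud (in the frame) is split into `n_slices`
equal-width intervals — geometric sections, not equal-count quantiles,
matching the idea of cutting the physical panicle into equal lengths.
Slice 1 is the top-most section. Interior boundaries are half-open
with boundary points assigned to the upper slice; the ends are closed,
so slices partition the cloud exactly: per-slice point counts and
channel sums add up to the whole-cloud totals by construction, and
reversing the up hint reverses the slice order. Empty slices are
reported with zero counts and flagged `NA` proportions. Per-slice
voxel counts share the whole-cloud voxel size so they are comparable
across slices. `profile_matrix()` averages replicate profiles into a
slice × condition matrix (ignoring flagged slices) for heat-map
rendering.

## Gas-exchange normalization

Whole-organ fluxes divided by area convert to the per-m² convention of
leaf instruments (10⁴ cm²/m², applied once). PPA — the sweep *mean* —
is the panicle normalizer; max/min areas are available for sensitivity
analysis. WUE = A/E requires E ≠ 0; percent change
100·(treated − control)/control requires a non-zero control; percent
fertility is 100·filled/(filled + sterile). The Pearson panel computes
r from `stats::cor` and p-values from the t transform at n − 2 degrees
of freedom, stratified by genotype × treatment × timepoint; no
multiple-testing correction is applied, matching the exploratory use
of such panels. Zero-variance traits yield flagged `NA`s. A reader
for CSV tables accepts either raw fluxes plus area (`A_raw`, `E_raw`,
`area_cm2`) or already-normalized `A`/`E` columns, since instruments
differ in what they export.

## The synthetic generator

`generate_panicle()` emulates the features the pipeline actually
exploits: a gently arced rachis (quadratic bend, so the principal axis
and the chord differ and the frame code is exercised off the trivial
case), primary branches bearing Gaussian spikelet blobs, an axial
green→red gradient (each point green-dominant with probability linear
in height between the programmed endpoints), and optional background
clutter blobs. The palettes — green ≈ (60, 180, 50) ± (15, 20, 15),
red with R/G swapped, gray as a shared per-point luminance
120 ± 10 with only ±2 channel jitter — are chosen so VARI separates
classes the way vegetation separates from an achromatic background.
The gray channels must be *correlated*: independent channel noise of
realistic magnitude would give a sizeable tail of spuriously "green"
background points, which is not how achromatic surfaces behave.
Defaults (rachis 17 cm, 10 branches × 8 spikelets × 60 points,
gradient 0.95→0.7, jitter 0.05 cm) give a ~9k-point cloud resembling a
temperate japonica panicle during grain fill. The gas-exchange design
uses typical rice baselines (flag leaf A 22, E 5; panicle A 6, E 2 —
panicle assimilation roughly 30% of the leaf) with heat-stress
multipliers at 10 days after fertilization encoding the headline
genotype contrast (−56%/−26% leaf/panicle for the sensitive genotype,
+57%/+121% for the tolerant one), n = 4 replicates and 8% CV noise.

What passing the synthetic suite shows: the geometry, conservation and
recovery properties of the *algorithms* — silhouette areas within 3–5%
of closed forms, exact partitioning, Jaccard ≥ 0.99 segmentation of
clean clutter, gradient recovery within 0.05 per slice. What it does
not show: robustness to reconstruction artifacts absent from the
generator — non-Gaussian outlier structures, color bleeding between
panicle and background, missing patches from occlusion, or clutter
that is itself green (a leaf touching the panicle would defeat a
purely colorimetric rule). Problem sizes in the tests (5×10⁴-point
primitives, ~10⁴-point panicles, 200 segmentation fixtures) were
chosen as the smallest that make the statistical tolerances
meaningful.

## Other conventions and limitations

- PLY I/O accepts ASCII and binary little-endian dialects,
  `red/green/blue` or `r/g/b` color names, and rescales 0–1 float
  colors to 0–255. Coordinates are stored as float32; ASCII output is
  quantized through float32 too, so both dialects reload identically.
- Cluster labels are 1-based, following R convention.
- An optional residual color filter after selection (for e.g. plant
  labels inside the panicle cluster) is available in spirit via
  re-running selection at a stricter threshold, but is deliberately
  not applied by default: on synthetic data it is unnecessary, and on
  real data it should be a conscious analyst choice.
- Slicing follows the PCA Z-axis. If the panicle droops strongly, the
  principal axis and the vertical diverge; pass an explicit frame to
  `slice_cloud()` to slice along the world vertical instead.
- The sweep's 36 areas are not independent measurements — adjacent
  angles share most of their information. PPA's value is as a stable,
  reproducible normalizer, not as a surface-area estimate; true 3D
  surface area from meshes is a non-goal.
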