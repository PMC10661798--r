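---
title: "Quantifying planar polarity and ciliary flow in multiciliated epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity and ciliary flow in multiciliated epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ependyflow)
```

## The measurement problem

Multiciliated ependymal cells line the brain ventricles and drive
near-wall cerebrospinal-fluid flow through the coordinated beating of
motile cilia. That coordination is visible as several nested forms of
planar polarity:

* **Translational polarity** — the patch of basal bodies (the organelles
  anchoring the cilia) sits off-center on the apical surface, displaced
  in a direction shared across the tissue. It is quantified by the
  distance **TD** between the cell centroid *C* and the basal-body patch
  centroid *BC*, and the direction **TA** of the vector *C→BC*.
* **Patch orientation** — the patch is elongated; its axis is measured
  as **Feret's angle FA**, the orientation of the longest caliper
  diameter **LD** of the basal-body point set.
* **Rotational polarity** — each basal body carries a lateral basal
  foot pointing in the cilium's beat direction. Vectors drawn from each
  basal-foot marker to the nearest basal-body marker report per-cilium
  orientation.
* **Flow directionality** — fluorescent microspheres placed over the
  ependymal surface move with the near-wall flow; the distribution of
  their per-particle movement directions distinguishes coherent,
  unidirectional transport from disorganized, turbulent transport.

In healthy tissue all four measures concentrate around a common
direction; when ciliogenesis is impaired they decohere — patches
centralize (small TD), patch angles and foot directions spread over the
circle, and microsphere directions lose their common mode. This package
implements the full measurement chain plus the circular statistics
needed to compare groups, and a synthetic-data generator that makes
every stage testable against known ground truth.

## Angle conventions

Degrees are the external unit everywhere (radians appear only inside
trig calls). Directions are measured counterclockwise from +x in a
y-up frame. Because image coordinates put the origin top-left with y
increasing downward, the direction of an image displacement `(dx, dy)`
is `atan2(-dy, dx)`. Directional quantities (TA, foot vectors, flow
directions) live on `[0, 360)`; axial quantities (FA, patch axes) are
defined modulo a half-turn and live on `[0, 180)`. Axial samples are
analysed by the standard doubling construction: double the angles,
compute circular statistics on the full circle, halve the mean. The
resultant length reported for an axial sample is that of the doubled
angles.

## The generative model

`generate_mosaic()` builds a synthetic ventricular-wall field with
known per-cell truth:

1. **Tissue geometry.** Cell territories are a discrete Voronoi
   tessellation of Poisson-disk seeds with one Lloyd relaxation step.
   This produces convex, roughly isotropic cells of similar size — the
   salient features of an ependymal mosaic — without claiming any
   specific biophysical tiling model. The label image is the partition
   itself (every pixel belongs to exactly one cell).
2. **Translational polarity.** Each cell's patch centroid is placed at
   `C + offset_frac * r_eq * (cos psi, sin psi)` with
   `psi ~ vonMises(mu_global, kappa_trans)`, where `r_eq` is the radius
   of the circle with the cell's area. The von Mises distribution is
   used as the canonical circular analogue of Gaussian noise; nothing
   in the measurements depends on that choice.
3. **Patch shape.** `bb_per_patch` basal bodies scatter in an ellipse
   (semi-axes `patch_ax`, `patch_bx` as fractions of `r_eq`) whose
   major axis follows an axial von Mises law around `mu_global`
   (sampled on doubled angles, halved). Within the ellipse the points
   keep a minimum separation `bb_min_sep` — basal bodies are physical
   organelles with lattice-like spacing, and keeping that spacing wider
   than the basal-foot length is precisely what makes
   "foot to *nearest* basal body" a well-posed pairing, in the data
   and in the simulation alike.
4. **Rotational polarity.** Each basal body gets one basal-foot point
   displaced by `foot_offset_px` in a direction
   `~ vonMises(mu_global, kappa_rot)`.
5. **Containment.** A patch whose points fall outside their cell is
   resampled (up to 25 attempts), then clipped toward the cell centroid
   and flagged `clipped` in the ground truth.

Point tables are authoritative and carry exact coordinates; the label
image is a rasterized view, so geometric tests run on coordinates and
rasterization error is bounded separately (the pixel-mass centroid of a
cell differs from the exact centroid by well under a pixel at the
default cell size of roughly 25 px equivalent radius).

Two presets encode the contrast the analysis is designed to detect.
`"wildtype"` uses `offset_frac = 0.35` and all concentrations at 8
(about 20 degrees circular standard deviation — visibly coordinated but
noisy, matching the look of a healthy field). `"mutant"` uses
`offset_frac = 0.10` and all concentrations at 0 (uniform): patches
nearly centered and randomly oriented. The mutant offset magnitude is a
calibration choice — reported mutant phenotypes are qualitative
("located more centrally", "randomly oriented") — and is fixed here
once; it is not tuned against any test.

One integer seed expands into independent per-component substreams
(seed placement, offset directions, axes, foot directions, scatter), so
adding or reordering one sampled component never perturbs the others,
and identical configurations reproduce byte-identical artifacts.

The flow generator (`generate_flow_video()`) advects point particles
with a direction field — constant for the `"coherent"` regime; a smooth
swirl about the domain center for `"disorganized"`, whose directions
span the full circle (truth resultant length near 0) — plus isotropic
Gaussian steps of scale `diffusion_px`, and renders each live particle
as a unit Gaussian spot. Particles leaving the domain are dropped from
subsequent frames. Initial positions keep a minimum separation (the
microsphere suspension is dilute) and a margin from the border.
Defaults — 100 particles, 50 frames, 2 px/frame, diffusion 0.3 px,
256 px field — are calibration choices at the scale of the recorded
videos; the source recordings' particle counts and frame rates are not
stated anywhere, so these values were fixed once as plausible and left
alone.

## The measurement chain

* `cells_from_label()` / `cells_from_polygons()` produce per-cell
  centroid, area, `r_eq` and a border flag. Cells touching the image
  border have truncated territories that bias centroids, so they are
  excluded from summaries by default (`include_border = FALSE`
  overrides).
* `measure_polarity()` joins cells with basal-body points: the patch
  centroid is the unweighted mean of the points (patches are marked as
  point sets; intensity weighting is out of scope), TD and
  `TD_norm = TD / r_eq` follow, TA is the *C→BC* direction (flagged
  `NA`, not an error, when TD = 0), and FA/LD come from
  `ferets_angle()`. Raw TD in pixels depends on magnification, so the
  normalized column is always emitted alongside it; which scale a given
  published axis uses is not always stated, and both are available.
  Whether Feret's angle should be read per patch or per basal body is
  ambiguous in the field's usage; the patch-level reading is the
  default, and `per_bb = TRUE` exposes a per-point-neighbourhood
  variant (axial mean of each basal body's 3-nearest-neighbour Feret
  angle).
* `ferets_angle()` computes the diameter over convex-hull vertices;
  ties at the maximum distance resolve to the smallest FA, making the
  output deterministic.
* `rotational_vectors()` pairs feet to basal bodies one-to-one,
  greedily by ascending distance, gated at `max_gate` (default twice
  the median foot-to-nearest-body spacing). Greedy gated matching
  prevents many-to-one collapse while staying transparent; unmatched
  feet are reported, never silently dropped. Ties break by lower point
  index.
* `summarize_cells()` reports n, mean ± SEM for TD and TD_norm,
  circular mean/resultant for TA (directional) and FA (axial), and —
  with two groups — a two-tailed Welch *t*-test on TD (the
  equal-variance assumption buys nothing here and Welch is the safer
  default).

For flow videos, `detect_particles()` finds local maxima of a
difference-of-Gaussians bandpass above a threshold *relative* to the
maximum response (so direction statistics are invariant to intensity
rescaling) and refines each to the intensity-weighted centroid of a
`2*sigma` window. `link_trajectories()` is greedy gated
nearest-neighbour linking with optional gap bridging — chosen over
global assignment for transparency at the low particle densities of
dilute microsphere preparations; the gate defaults to three times the
median per-frame step. A track's direction is its net first-to-last
displacement (robust to per-frame jitter; the per-step circular mean is
also computed as a secondary column), and tracks with net displacement
under `min_disp` (default 2 px) are excluded as Brownian-only.
`compare_flow()` hands the two direction samples to Watson's test.

## Circular statistics

`circular_mean_R()` is the unit-vector mean; a resultant length below
1e-12 flags the mean as undefined rather than returning an arbitrary
direction. `rayleigh_test()` uses `Z = n R^2` with the standard series
approximation for its p-value (flagged below n = 5).

Watson's two-sample U² statistic is computed from the pooled sort:
with `d_k` the difference of the two empirical CDF fractions at the
k-th pooled order statistic,

U² = (n·m/N²) · [ Σ d_k² − (Σ d_k)²/N ].

It is invariant to joint rotation of both samples (the right property
for comparing direction distributions whose zero is arbitrary) and
symmetric in the sample labels. Ties — possible with rounded angle
data — use the average-rank convention: `d` is averaged within each
tie block; an exhaustive-relabeling oracle at small n validates that
convention in the tests. The p-value is by random relabeling of the
pooled sample by default, `p = (1 + #{U²* ≥ U²}) / (B + 1)` with
B ≥ 999 — valid at any sample size, which matters because published
uses of the test rarely state whether an exact or asymptotic p was
used. The asymptotic method compares U² with the large-sample critical
points (0.152, 0.187, 0.268, 0.385 at α = 0.10, 0.05, 0.01, 0.001) and
reports the bracket, with the conservative upper bound as `p_value`
and a flag when min(n, m) < 8.

Rose-plot binning uses half-open bins `[k·w, (k+1)·w)`; 24 bins is the
default for directional data (a bin count for published circular bar
plots is rarely stated; 15-degree bins are conventional), and axial
plots halve the bin count to keep the same width.

The cohort module is deliberately small: `allele_frequency()` is the
carrier-count arithmetic (1 heterozygote among 53 diploid individuals
gives 1/106 ≈ 0.0094), and `yates_chi2()` is the 2×2 chi-square with
continuity correction, clamped to zero when the correction overshoots
(`|ad − bc| ≤ N/2`), with p from the χ²₁ survival function. The
general-population comparison requires external allele counts (e.g.
from gnomAD); those are inputs, never reconstructed.

## Numerical and design notes

* Pixel centers sit at half-integer coordinates `(col − 0.5,
  row − 0.5)`; the renderer and the detector share this convention, so
  positions round-trip without a half-pixel bias.
* `polygon_centroid()` rejects zero-area polygons (|area| < 1e-12);
  `ferets_angle()` requires two distinct points and treats distances
  within a 1e-12 relative band as tied.
* Degenerate inputs flag rather than throw where the meaning of the
  measurement allows it: TA at TD = 0 is `NA`; a circular mean at
  R ≈ 0 is `NA`; a single-point patch has no FA/LD.
* Determinism: every sampled quantity flows from one integer seed via
  fixed substream derivation; permutation tests take an explicit seed
  and restore the caller's RNG state.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure the measurements
assume — offset patch centroids with von Mises spread, elongated
patches, foot vectors around a global direction, coherent versus
disorganized advection with Brownian noise — with exact ground truth.
It deliberately omits photometric realism: no point-spread function,
no shot or background noise, no uneven illumination, no 3-D curvature
of the ventricular wall, no cilia beat dynamics, and no segmentation
errors (cell boundaries are taken as given, as they are when boundaries
are traced manually). Passing tests therefore demonstrate that the
measurement chain is correct *given* segmented cells and marked points,
and that the statistical machinery has its stated size and power; they
do not certify robustness to segmentation or staining artefacts.

Problem sizes in the test-suite simulations (200-cell mosaics at
640×640 px; 1000 null pairs at n = m = 30 for permutation calibration;
500 power replicates at n = m = 100; 50-frame videos of 100 particles)
were chosen as the smallest sizes at which the checked properties are
statistically stable, and the noise-free end-to-end tracking check
spawns particles away from the frame border, where truncated spots
would bias sub-pixel centroids — an analysis limitation that is real
for data too and is flagged by the border conventions above.

## Known limitations

* The mosaic is 2-D and convex-celled; strongly curved or elongated
  ependymal cells are not emulated.
* Greedy linking can fragment tracks when particles pass within the
  gate of one another; fragments still contribute directions if they
  clear `min_disp`, which slightly inflates n without biasing the
  direction distribution under either regime.
* The asymptotic Watson p-value is a bracket, not a continuous value;
  use the permutation method when an exact figure matters.
* FA of a near-isotropic patch is high-variance by construction (the
  longest diameter of a round point cloud is direction-unstable); the
  axial resultant length reported alongside the mean is the guard
  against over-reading it.
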