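---
title: "Quantifying vascularized tumor spheroids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascularized tumor spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Vascularized tumor spheroids (VTSs) are self-organized 3D co-cultures of
tumor cells, fibroblasts, endothelial cells and macrophage-like cells in
which the endothelial compartment assembles into a CD31-positive
*pseudovasculature* (PV): connected networks of tubular segments that
respond to anti-angiogenic and vascular-disruptive drugs much like tumor
vessels do. Light-sheet microscopy of cleared, immunostained VTSs yields
multichannel 3D stacks; this package turns such stacks into a
quantitative, comparable description of each spheroid and into a
calibrated ranking of drug effects. Because public raw stacks of this
kind are not available, the package ships a seeded phantom generator that
produces stacks *with known ground truth*, so every stage of the pipeline
is validated against geometry that is known exactly.

This vignette documents the models, the tunable parameters, and the
places where the design was genuinely open, so that a user can judge what
the outputs mean and what the validation does and does not show.

## The pipeline at a glance

1. **Preprocessing** (`median_filter_3d`, `combined_channel`,
   `vts_surface_mask`): per-channel 3D median denoising, an additive
   combined channel, and delineation of the spheroid body.
2. **Segmentation** (`segment_channel`, `detect_cells`): per-channel
   foreground masks with connected-object statistics, and detection of
   point-like cells at a nominal 10 µm diameter.
3. **Vessel tracing** (`trace_vessels`): skeletonization of the CD31
   mask into networks, segments, diameters and branch levels.
4. **Distance analysis** (`pv_distance_field`, `supply_index`,
   `cell_distances`, `coliv_association`): anisotropic Euclidean
   distance fields from the PV, the supply index, per-cell distances,
   and Col IV basement-membrane association.
5. **Description** (`compute_descriptors`): a versioned registry of
   named per-VTS parameters (71 with the full staining panel, 46 with
   the three cellular channels).
6. **Ranking** (`fit_vei_model`, `compute_vei`, `effect_indices`):
   calibration of the Vascular Effect Index against observer scores and
   bounded compartmental effect indices.
7. **Statistics** (`pca_descriptors`, `interassay_sdm`, `welch_ttest`):
   standardized PCA, inter-assay reproducibility, group comparisons.

The numbered scripts under `analysis/` run these stages as a narrative
workflow on the synthetic materials and write their tables under
`results/`.

## Coordinate and intensity conventions

Voxel arrays are indexed `(z, y, x)` with physical position
`(index − 1) × spacing` µm, i.e. voxel centres on a grid anchored at the
origin; all distances, lengths, diameters and volumes are reported in
micrometres (µm, µm³). The default spacing follows the acquisition
geometry of light-sheet stacks (coarser in z than in xy). Channels are
treated independently and are never globally normalized — in practice
staining intensity varies between sessions and only the
signal/background thresholds are adapted, which is exactly what
`pipeline_config()` exposes.

## Preprocessing

**Median filter.** The "setting 2.0 per axis" of the commonly used 3D
median filter is interpreted as a box of half-width 2 voxels per axis
(5×5×5) with replicated edges, which reproduces the reference tool's
neighborhood convention. The filter is exercised against a brute-force
per-voxel median oracle in the test suite. Note that the physical extent
of the box scales with the voxel spacing; on coarse grids a 5×5×5 box
erases structures thinner than about two voxels, which constrains how
thin the phantom's vessels may be made relative to its grid.

**Combined channel and VTS surface.** All fluorescence channels are
summed (saturating at the intensity ceiling) and the spheroid body is the
largest 26-connected component above threshold after Gaussian smoothing,
with interior holes filled (6-connected background, the standard
complementary-connectivity pairing). A *surface detail* of *d* µm is
implemented as Gaussian pre-smoothing with σ = *d*/2: the reference
implementation is proprietary, so the package fixes a documented,
testable surrogate with the same single length-scale parameter. Defaults:
10 µm for the VTS body, 2 µm for individual channels. The VTS threshold
rule is not specified anywhere authoritative; the default is Otsu's
threshold on the smoothed combined channel, overridable per channel with
absolute or quantile rules.

## Segmentation and cell detection

Per-channel segmentation smooths at the channel surface detail,
thresholds, restricts to the VTS body, drops objects below
`min_object_volume` (default 50 µm³, about one tenth of a 10 µm cell) and
labels 26-connected components. Composition fractions are computed
per-channel over the VTS volume and renormalized across the three
cellular compartments; overlapping positive voxels are *not* made
exclusive, since channels are segmented independently.

Cell detection is Laplacian-of-Gaussian blob detection at the scale of
the configured cell diameter (σ = d/(2√3), the LoG radius-matching
relation), with 26-neighborhood local maxima above a response threshold
(`cell_quality`, intensity units; default 10 — on the phantom, true 10 µm
orbs respond at 80–95 while blurred noise stays below 1) and sub-voxel
refinement by a background-subtracted response-weighted centroid. On
*dense* channels (tumor, fibroblast), individual cells are not resolvable
and detection degrades to a deterministic texture-maximum count; the
descriptor table still records it, but single-cell accuracy is only
claimed — and only tested — for orb-like populations with at least 15 µm
separation, where the phantom recovery tests require exact counts and
centroid errors below 2 µm.

## Vessel tracing

The CD31 mask is thinned to a one-voxel curve skeleton by sequential
topology-preserving thinning (six directional sub-iterations; a border
voxel is deleted only if it is *simple* — one 26-connected foreground
component in its neighborhood and one 6-connected background component
touching a face — and not a curve endpoint). Skeleton voxels condense
into a graph: junction clusters and endpoints become nodes, maximal
branch-free voxel chains become segments. Spurs shorter than
`prune_length` (default 5 µm, roughly one PSF-blurred voxel artifact at
acquisition resolution) are removed and the graph rebuilt; pruning at 0
is the identity.

Skeletonization runs on the voxel grid while all lengths are computed in
µm; for strongly anisotropic spacing this is an approximation (the
thinning criterion itself is metric-free), which is the standard
trade-off of grid thinning. Segment radii are the anisotropic Euclidean
distance from each skeleton point to the nearest background voxel
centre; the voxel-centre convention biases radii upward by at most about
half a voxel diagonal, which stays inside the one-in-plane-voxel
tolerance the recovery tests assert.

**Branch levels.** Per network, the *main branch* is the
endpoint-to-endpoint path of maximal total length — on a maximum-length
spanning tree if the network contains anastomoses — with ties broken by
the lexicographically smallest endpoint-id pair. Its segments carry level
0; every other segment's level is one more than the smallest level among
the segments it attaches to (chord segments of cycles are levelled after
the tree). A brute-force oracle that enumerates all endpoint paths
verifies this on random trees with up to 30 segments.

**Segments per network (S/N).** The per-VTS scalar is the *mean* number
of segments over networks; the aggregation rule (mean vs. max vs. total)
is not fixed anywhere authoritative, and the mean is the only choice
that stays comparable when fragment counts differ between spheroids.

## Distance analysis

The PV distance field assigns every in-VTS, non-PV voxel its anisotropic
Euclidean distance (µm) to the nearest PV voxel centre (Felzenszwalb
separable transform, verified against exhaustive search). Voxels outside
the VTS carry an explicit out-of-domain value (NA) rather than a
saturated gray value, so histograms are never contaminated; only the
optional 8-bit export uses the 255-as-outside convention for visual
inspection. An empty PV mask yields an Inf "no vessel" sentinel with a
warning, not an error.

The **supply index** is defined as

SI = (relative CD31⁺ volume in %) / (median in-VTS PV distance in µm),

so a denser and more homogeneously distributed pseudovasculature scores
higher. The verbal definition this implements ("indexed by the fraction
of the volume percentage … and the median distance") is ambiguous between
this ratio and its reciprocal; the ratio was chosen so that *higher SI =
better supply*, which also makes the negative weight the calibration
assigns to the SI ratio interpretable (a treated/control SI ratio that
rises while volume and complexity fall signals pruning rather than
improvement). This is a documented reading, not an asserted fact about
the original tooling.

Col IV voxels are partitioned into PV-associated (within `d_assoc`,
default 3 µm — the apposition distance of a basement membrane at this
resolution, exposed in the config), in-VTS non-associated, and
outside-VTS; cell-to-structure distances are exact nearest-voxel-centre
distances (an EDT-bounded local search keeps them exact at full-stack
scale).

## The descriptor registry

The per-VTS description is a versioned registry of named parameters in
families: size, composition, cell statistics, PV network, distance
field, macrophage (CD11b), ECM (Col IV) and hypoxia (Hif1α). The full
panel defines **exactly 71** parameters; the three-cellular-channel
subset defines **exactly 46**. The registry cardinality is a contract:
absent channels drop whole families (never single silent NAs), mixed
registry versions refuse to pool, and the identity of every parameter is
documented in `parameter_registry()` with units and required channels.
The exact itemization of the original 71-parameter panel is not public;
this registry reproduces its structure (the families the main analyses
use) rather than its letter, and any future reconciliation is a version
bump.

## Observer scores and the VEI

Observer ratings are five-tier grades; the canonical internal scale is
{−1, −0.5, 0, +0.5, +1}. Published materials state the tiers both as
±1/±0.5 and as ±2/±1 in different places; the package canonicalizes to
[−1, 1] — which matches the magnitudes of reported scores and indices —
and imports ±2-scaled files via `scale = "two"` (divided by 2). The
observer score (OS) of a group is the plain mean of all its ratings.

The Vascular Effect Index is the power-law combination

VEI = x₁·(V_T/V₀)^y₁ + x₂·(SI_T/SI₀)^y₂ + x₃·((S/N)_T/(S/N)₀)^y₃

of treated/control ratios of PV volume, supply index and segments per
network; the reference calibration is x = (0.6, −0.11, 0.44),
y = (0.65, 1.5, 1.5), giving VEI = 0.93 at identity ratios. Ratios are
ratios of group means (means are what the source figures display).

**Calibration.** `fit_vei_model` follows the stepwise scheme: ordinary
least squares for the weights with exponents fixed at 1, then bounded
Levenberg–Marquardt refinement of all six parameters (exponents started
at 1, bounded to [0.1, 5]). One design decision matters here: observer
scores live on a *bounded* scale while the power-law VEI is unbounded —
on ratio ranges spanning [0.25, 4] the reference model reaches values
near 5, so a large fraction of strongly affected groups sits pinned at
the scale limit. A score at the limit says only "at least this extreme";
treating it as an exact observation drags the fit toward a flattened
model and the calibration becomes unrecoverable. The fit therefore
treats |OS| ≥ 1 as censored and excludes those groups (with a message;
`censor_bound = Inf` disables). With 200 synthetic groups and score
noise of 0.02, the recovered weights land within ±0.02 and the exponents
within ±0.07 of the generating values; the acceptance tolerances are
±0.05 and ±0.15. For the same reason, held-out agreement between
predicted VEI and OS is evaluated on uncensored groups, where it exceeds
r = 0.98 at noise 0.05.

**Effect indices.** No functional form is fixed by the source for the
compartmental indices beyond being scaled to [−1, 1]; the package uses
the bounded antisymmetric map b(r) = (r − 1)/(r + 1) of treated/control
ratios (0 at no change, ±1 asymptotically), with signs chosen so the
named effect scores positive: anti-angiogenic = −b(relative CD31
volume), vascular-disruptive = −b(total PV length), tumor-cell and
fibroblast indices = mean of b(density) and b(relative volume).

## Statistics

PCA standardizes each parameter (zero-variance columns are dropped with
a message) and fixes component signs by making the largest-magnitude
loading positive, so outputs are deterministic. The inter-assay SDm of a
parameter is the standard deviation of per-experiment means over the
absolute grand mean, in percent, undefined (flagged) at a zero grand
mean. Group comparisons always report the Welch/Satterthwaite-corrected
two-tailed test; the pooled Student variant is available explicitly
rather than via a variance pre-test, a deliberate simplification of the
"if necessary, Welch" convention that avoids a data-dependent test
choice.

## The phantom: what it emulates, and what it does not

`phantom_spec()` fixes the synthetic study conditions:

| parameter | default | rationale |
|---|---|---|
| spheroid radius | 150 µm | lower end of the 300–500 µm diameter range, so a ~256-voxel-wide grid covers it |
| voxel spacing | (2, 1.3, 1.3) µm | anisotropic like light-sheet stacks; full acquisition resolution (1, 0.5, 0.5) µm would need ~10⁹ voxels per spheroid |
| vessels | 3 roots, branch prob. 0.12/step, radii 4–9 µm, step 8 µm, depth ≤ 4 | random recursive trees with direction persistence; produces diverse diameters and branch levels; radii sit in the lower part of the observed PV diameter range while staying above the median-filter erasure limit of the grid |
| cells | 25 CD11b and 25 Hif1α orbs of 10 µm; tumor/fibroblast as complementary dense compartments | orbs match the "cells as 10 µm orbs" representation; dense compartments emulate unresolvable cell masses |
| noise | Poisson (photon scale 2) + Gaussian (sd 3) on 0–255 intensities over background 10, PSF σ = 1 µm, 8-bit output quantization | generic fluorescence forward model with camera quantization, strong enough to stress thresholds (tube SNR ≈ 10) |

Orbs are hard spheres placed by rejection sampling (error after 10⁴
attempts); ground-truth masks are the noiseless rasterizations, bitwise
reproducible from the seed. A straight-tube helper at acquisition
spacing (1, 0.5, 0.5) µm exercises the diameter and length claims at the
instrument's own resolution.

The phantom deliberately does **not** emulate: clearing and
refractive-index artifacts, light-sheet stripe shadowing, depth-dependent
attenuation, lumenized vessels, nucleus-level texture in dense
compartments, or biologically realistic network topology (anastomoses
occur only where random trees touch). Passing the recovery tests
therefore shows that the *operations* are correct and well-calibrated on
geometry of known truth at realistic noise — it does not certify
segmentation quality on real cleared-tissue stacks, where threshold
choices dominate.

## Problem sizes and determinism

The validation suite runs the full pipeline on a 166×255×255 reference
phantom (the in-plane extent matches a 256-class grid at 1.3 µm
spacing), unit tests on ~80–110-voxel grids, and oracle comparisons on
≤ 32³ random instances over 100 seeds; the archetype-reproducibility
analysis uses nine 60 µm-radius phantoms at (2.5, 2, 2) µm spacing.
These sizes were chosen so the whole suite completes on a single CPU in
well under half an hour while still exercising the full-size code paths.
Every stochastic step is seeded: phantoms are pure functions of their
spec (including the seed), the ranking generator of its seed argument,
and the two optimizer stages are deterministic from their initial
values.

## Known limitations

- Grid thinning on anisotropic voxels approximates the metric skeleton;
  strongly flattened voxels (dz ≫ dx) will bias branch geometry.
- Diameters are voxel-centre distances: sub-voxel precision is not
  claimed below about half a voxel.
- Otsu defaults assume clearly bimodal channels; faint staining needs
  explicit thresholds, as in the original per-session adjustments.
- Cell counts on dense channels are texture statistics, not cell counts.
- The effect-index map b(r) is one defensible choice among several; only
  its qualitative ordering, boundedness and sign conventions are
  specified behavior.
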