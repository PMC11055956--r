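# vtsquant

Quantitative image analysis and drug-effect ranking for vascularized
tumor spheroids (VTSs).

VTSs are self-organized 3D co-cultures of tumor cells, fibroblasts,
endothelial cells and macrophage-like cells in which the endothelial
compartment forms a CD31⁺ *pseudovasculature* (PV) — connected networks
of tubular segments that react to anti-angiogenic and
vascular-disruptive drugs much like tumor vessels. Light-sheet
microscopy of cleared, stained VTSs produces multichannel 3D stacks;
this package provides the full downstream analysis for screening labs
working with such data:

- **preprocessing** — 3D median denoising, additive combined channel,
  spheroid-body delineation;
- **segmentation** — per-channel compartment masks with connected-object
  statistics, and 10 µm-scale cell detection (Laplacian-of-Gaussian);
- **vessel tracing** — topology-preserving skeletonization of the CD31
  mask into networks, segments, per-segment mean diameters and branch
  levels relative to each network's main branch;
- **distance analysis** — anisotropic Euclidean distance fields from the
  PV, distance histograms, the PV supply index, cell-to-structure
  distances, Col IV basement-membrane association;
- **description** — a versioned registry of named per-VTS parameters
  (exactly 71 with the full staining panel, 46 with the three cellular
  channels);
- **ranking** — observer-score aggregation and calibration of the
  Vascular Effect Index

  VEI = x₁·(V_PV,T/V_PV,0)^y₁ + x₂·(SI_T/SI_0)^y₂ + x₃·((S/N)_T/(S/N)_0)^y₃

  (reference calibration x = (0.6, −0.11, 0.44), y = (0.65, 1.5, 1.5)),
  plus bounded [−1, 1] compartmental effect indices;
- **statistics** — standardized PCA, inter-assay SDm, Welch tests;
- **phantoms** — a seeded synthetic VTS generator with complete ground
  truth (centerlines with radii, masks, centroids), so every stage is
  testable without microscope data.

## Worked example

`analysis/01_simulate.R` … `04_ranking.R` run the whole workflow on
synthetic materials and write tables under `results/`. The core of it,
by hand — generate a full-channel phantom, describe it, and check the
recovery against ground truth:

```r
library(vtsquant)

ph  <- generate_phantom(reference_phantom_spec(seed = 1))
row <- compute_descriptors(ph$stack, pipeline_config(), sample_id = "ref")
```

On the reference phantom (150 µm spheroid, 166×255×255 voxels at
2×1.3×1.3 µm, three vessel trees totalling 6088 µm of centreline, 25
CD11b and 25 Hif1α orbs) this prints, via `analysis/02_quantify.R`:

```
VTS volume        1.41e+07 um^3 (sphere truth 1.41e+07)
CD31 Dice         0.894
traced PV length  6189 um (truth 6088, +1.7%)
PV networks 1, segments 166, mean diameter 7.7 um
median PV distance 26.9 um, supply index 0.0790
CD11b cells 25 / 25, Hif1a cells 25 / 25
```

i.e. the spheroid volume is recovered essentially exactly, the vessel
mask overlaps the truth at Dice 0.89, the traced skeleton length is
within 1.7 % of the generated centrelines, and both orb populations are
found completely. `row` is a one-row data frame with 71 named
parameters (`parameter_registry()` lists them with units).

Calibrating the VEI on a synthetic observer-score dataset
(`analysis/04_ranking.R`; 200 groups, ratios log-uniform in [0.25, 4],
score noise 0.02):

```
Stage-1 OLS weights: x1=0.414 x2=-0.217 x3=0.710
Stage-2 fit:  x1=0.576 y1=0.674 x2=-0.097 y2=1.587 x3=0.454 y3=1.442
Generating model: x1=0.600 y1=0.650 x2=-0.110 y2=1.500 x3=0.440 y3=1.500
Held-out VEI vs OS: Pearson r = 0.997 (20 uncensored groups)
```

Groups whose score sits pinned at the ±1 grading-scale limit are
treated as censored and excluded from the fit (see the vignette for
why); the recovered weights land within ±0.03 and the exponents within
±0.09 of the generating model.

## Layout

```
R/, src/            package code (one file per pipeline stage; Rcpp kernels)
analysis/01..04     narrative workflow over the package, writes results/
scripts/acceptance.R  headline-quantity reproduction (JSON output)
tests/testthat/     unit + property + end-to-end recovery tests
vignettes/          methods vignette: models, parameters, design choices
```
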