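---
title: "Methods: hybrid-contrast segmentation and SWI radiomics for parkinsonian syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid-contrast segmentation and SWI radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmap)
```

## The problem

Atypical parkinsonian syndromes — the parkinsonian and cerebellar variants
of multiple system atrophy (MSA-P, MSA-C) and progressive supranuclear
palsy (PSP) — present with motor signs that mimic Parkinson's disease (PD),
yet carry different prognoses and treatments. Each syndrome deposits iron
in the deep gray nuclei with a characteristic topography: MSA-P shows
posterolateral putaminal hypointensity with a lateral-to-medial gradient on
susceptibility weighted imaging (SWI); PSP shows anteromedial pallidal
hypointensity; PD at most a nonspecific slit-like hypointensity along the
lateral putaminal margin, a sign that also appears with normal ageing.
Because the slit is nonspecific, signal intensity alone cannot separate
MSA-P from PD; the *spatial pattern* can. `ironmap` implements an automated
pipeline that turns those patterns into a classifier: hybrid-contrast
(HC) fusion of T1w and SWI, template-driven deep-gray-matter (DGM)
segmentation on the fused image, 3D radiomic texture extraction from the
putamen, Fisher-score feature selection, and a repeated-split evaluation
harness over ten standard classifiers.

## The model, stage by stage

### White-matter intensity normalization

T1w scanner units are arbitrary, so every subject is rescaled by one
global factor so that the mean intensity over the white-matter mask equals
110. The operation is linear and idempotent; a volume already at the
target is returned unchanged. The WM mask is an input (any segmentation
source); the package does not re-derive it.

### Hybrid-contrast fusion

The HC image is the voxelwise linear combination

$$HC = w_1 \cdot T1w + w_2 \cdot SWI,$$

with the weights chosen so that the HC mean intensities in the putamen and
globus pallidus match a reference template's means in the same structures
as closely as possible — the least-squares solution of the 2x2 system
whose rows are the two structures and whose columns are the two
modalities. With a non-singular system this is an exact linear solve and
the residual is zero, which the tests verify against a general
least-squares routine. Collinear columns (SWI proportional to T1w in both
ROIs) are rejected with a diagnostic rather than solved unstably. Weights
are unconstrained in sign by default because the objective does not
require positivity; a flag can enforce it. The ROI means on the subject
side come from the *initial*, T1w-derived DGM mask — the fused image does
not yet exist when the weights are computed.

The rationale for fusion is asymmetric information: T1w delineates cortex
and global geometry but has weak, iron-insensitive DGM contrast; SWI shows
iron-rich nuclei strongly but little else. The fused image carries both,
so registration driven by it can follow iron-defined boundaries that T1w
alone does not see.

### Template label propagation

DGM labels live on the template. A deformation provider abstracts the
template-to-subject correspondence: the in-repo default estimates an
affine transform by registering the subject HC to the template
(multi-resolution maximization of normalized mutual information by a
whole-voxel basin scan plus coordinate descent with step halving — the
binned-histogram metric is piecewise-flat at sub-voxel steps, which
defeats simplex-style local search; metric, transform family, pyramid
and iteration budget are configurable),
while externally computed dense displacement fields on the template grid
are accepted for non-linear engines. Labels are transported by
nearest-neighbor sampling through the inverse mapping — labels are never
interpolated, so no label value can be invented. Diffeomorphic
registration itself is deliberately out of the package's scope: it is
mature external tooling, and the affine engine suffices for the affinely
generated phantoms used in validation.

### Radiomic extraction

Features are computed from SWI inside the putamen (merged across
laterality to maximize voxel support at the largest neighbor distance).
Intensities are discretized with a fixed bin width of 25 units —
`level = floor((x - min)/25) + 1` — the de-facto default of radiomics
tooling; the width is configurable. The full vector has 178 entries:

| family | count | distances |
|---|---|---|
| first-order | 19 | — |
| shape (3D) | 16 | — |
| shape (2D, largest axial slice) | 10 | — |
| GLCM | 24 x 3 = 72 | 1, 4, 7 voxels |
| GLRLM | 16 | 1 |
| GLSZM | 16 | 26-connected zones |
| NGTDM | 5 x 3 = 15 | 1, 4, 7 voxels |
| GLDM | 14 | 26-neighborhood |

Distance-parameterized families (GLCM, NGTDM) probe iron texture at
short, medium and long range; distances are measured in voxels along the
13 unique 3D directions with symmetric accumulation, and per-angle
features are averaged over directions. An ROI too small to support a
distance flags that distance (its features become `NA`) instead of being
silently dropped. Because SWI intensity is not a quantitative
susceptibility measure, the scale-reading first-order statistics
(minimum, maximum, mean, median, the 10th/90th percentiles, range, RMS,
total energy) are tagged signal-based and excluded from selection; the
exact membership of that exclusion list is an assumption made visible in
configuration.

Numerical choices worth knowing: `Imc2` and `MCC` are defined as 0 for
single-level ROIs; NGTDM Coarseness guards its reciprocal with 1e-30;
zero-denominator NGTDM Busyness/Strength are 0. The 3D surface mesh is
built by marching tetrahedra over a lightly smoothed copy of the binary
ROI (two passes of a separable 1/4-1/2-1/4 kernel, iso-level 0.5, linear
edge interpolation). Meshing the raw binary mask — with this or any
standard marching scheme — overestimates a digitized ball's surface
through staircase facets, badly enough to push sphericity outside any
reasonable calibration band; on the smoothed field the test suite holds a
radius-8 ball within 5% of unit sphericity, with a wide margin in
practice. ROIs of a few voxels, which the smoothing would
erase entirely, fall back to the binary mesh. Maximum-diameter features
measure between boundary-voxel centers. The 3D shape set totals 16 names:
the 14 standard descriptors plus the two compactness variants.

### Feature selection

For a two-class training table, each feature is scored by the Fisher
criterion

$$F_r = \frac{\sum_c n_c (\mu_{rc} - \mu_r)^2}{\sum_c n_c \sigma^2_{rc}},$$

with population class variances (configurable), infinities permitted when
a feature is constant within classes but split between them, and ties
broken by original column order so rankings are reproducible. The top 10
features enter classification. Selection only ever sees the training
rows; the interface makes leakage structurally impossible, and a harness
test corrupts held-out rows to prove the fitted state does not move.

### Classification harness

Six pairwise disease tasks arise from the four classes. For each task and
each of the repeated stratified 7:3 splits: z-score standardization is
fitted on the training rows; Fisher selection picks 10 features from the
training rows; each of the ten classifiers (kNN, linear SVM, RBF SVM,
Gaussian process, random forest, decision tree, MLP, AdaBoost, Gaussian
naive Bayes, QDA) is tuned by stratified 3-fold cross-validation over a
small fixed grid and refit on the full training set. Training metrics are
the out-of-fold CV metrics at the chosen hyperparameters — a training
estimate that can legitimately fall below the test estimate, as the
reported tables of such studies show — and a flag switches to
resubstitution if wanted. Metrics are sensitivity, specificity, balanced
accuracy, accuracy (direct confusion-count substitution; a zero
denominator yields a flagged `NA`, never a silent 0) and AUC via the
midrank Mann-Whitney equivalence. The master seed derives every repeat's
split seed, fold seed, and fitter seed, so a report is bit-reproducible.
Nine of the ten fitters wrap standard libraries (`class`, `e1071`,
`kernlab`, `randomForest`, `rpart`, `nnet`, and a shrinkage-regularized
QDA built on base linear algebra); AdaBoost is a discrete SAMME loop over
depth-1 `rpart` stumps because no installed library provides it. The
bespoke science lives in the harness, not the fitters.

## The phantom generator

Patient SWI is not distributable, so validation runs on seeded phantoms
that emulate the study conditions: bilateral putamen and globus pallidus
ellipsoids inside a white-matter brain ellipsoid, 64^3 voxels at 1 mm
isotropic (a compromise grid that keeps the putamen ~3000 voxels — enough
to support distance-7 texture — while a full cohort generates in
seconds). Iron appears as SWI hypointensity subtracted from a baseline of
100 against WM 120:

* **MSA-P** — a posterolateral wedge penetrating inward from the putaminal
  margin with a lateral-to-medial gradient, plus a milder deposit in the
  lateral pallidum adjacent to the putamen. The wedge is deliberately a
  *marginal* structure: the MSA-P/PD difference lives within a few voxels
  of the lateral boundary, so ROI placement genuinely matters, as it does
  clinically.
* **PSP** — anteromedial pallidal hypointensity.
* **PD** — extra depth on the slit only.
* **MSA-C** — mild diffuse putaminal change.
* **all classes** — a slit-like lateral putaminal hypointensity of random
  amplitude, the generic age-related mineralization sign. This shared
  component is what makes the MSA-P vs PD task non-trivial: intensity at
  the lateral margin alone cannot decide it.

Per-subject heterogeneity mirrors a clinic population: disease severity
multiplies the class deposit by U(0.1, 1) (early cases sit near the noise
floor), mineralization amplitude varies by U(0, 1.5), geometry jitters by
±2 voxels translation and ±3% scale (with an optional further jitter of
the nuclei *relative to the brain*, emulating anatomical variability of
DGM position that global alignment cannot absorb), and the raw T1w
scanner scale varies by ±20% (removed by WM normalization). Gaussian noise of sd 8 — roughly a
third of the deepest deposit, i.e. clearly visible but not clean — is
smoothed with a small separable kernel as a point-spread surrogate and
added to the *crisp* structural image, so deposit topographies remain
analytically exact and tests can verify rendered quadrant means in closed
form. T1w carries only 10% of the deposit field (as brightening), making
it nearly iron-blind; that asymmetry is what gives HC fusion genuine value
to detect. The template is the noise-free, disease-free anatomy with
typical template-like DGM contrast.

What the phantoms do *not* emulate: real anatomy (geometry is parametric),
susceptibility physics (no phase, no dipole convolution), non-affine
anatomical variability, scanner artifacts, and multi-site effects. Passing
the phantom suite therefore shows the pipeline's machinery is correct and
that the method's central mechanism — iron-reflecting masks preserving
marginal texture that degraded masks dilute — operates in the intended
direction; it does not certify clinical performance.

## Validation design

Every texture matrix is checked against brute-force enumeration (plain
nested loops over voxel pairs, runs, zones, neighborhoods) on dozens of
seeded ROIs, and the co-occurrence feature formulas against an
independent re-derivation; closed forms pin the degenerate cases. The
end-to-end check generates the 34/56 MSA-P/PD phantom cohort, runs the
full pipeline three ways — propagated HC masks, a deliberately
shifted-and-dilated surrogate of a T1w-only atlas mask, and permuted
labels — and requires the HC masks to beat the surrogate on mean test AUC
(RBF SVM, 20 repeats of the 7:3 split; 20 rather than 100 keeps the suite
fast, at the cost of a noisier mean) while permuted labels stay at
chance. A zero-effect cohort must keep all ten classifiers at chance
level, and the default-effect cohort must push the RBF SVM above 0.9 test
AUC.

## Known limitations

* The affine deformation engine cannot follow non-affine anatomy; real
  data should supply external displacement fields.
* Angle sets are fixed to the 13 unit directions scaled by the distance;
  tooling that enumerates all offsets of a given Chebyshev norm will give
  slightly different distance-4 and distance-7 co-occurrence values.
* Discretization settings (bin width 25) interact with SWI scaling;
  because SWI units are arbitrary, cross-scanner use should revisit the
  width.
* Small putamina can fail to support distance-7 pairs; the flag mechanism
  reports this, but downstream selection must handle the `NA`s (the
  phantom cohort never triggers it).
* QDA on 10 features needs tens of subjects per class; the shrinkage
  fallback keeps it defined, not well-calibrated, for smaller groups.
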