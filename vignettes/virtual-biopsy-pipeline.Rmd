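---
title: "Tile-based CMS prediction and the virtual-biopsy simulator: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based CMS prediction and the virtual-biopsy simulator: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidecms)
```

## The problem

Colorectal tumours fall into four transcriptome-defined consensus molecular
subtypes (CMS1 immune, CMS2 canonical, CMS3 metabolic, CMS4 mesenchymal)
with distinct prognosis and, plausibly, distinct treatment response. RNA is
not always available from routine material, so an alternative is to predict
the subtype directly from the H&E-stained slide image. `slidecms`
implements such a pipeline at desk scale: the three-stage
tile-classify-aggregate architecture, five-fold ensembling with a "mixed"
fallback call, a macro one-vs-rest AUROC evaluation layer, an adjusted
odds-ratio analysis linking subtype calls to pathological complete response
(pCR), and a virtual-biopsy sampling simulator that asks how many biopsy
fragments are needed before biopsy-based calls track resection-based calls.

Everything is testable end to end on synthetic imagery: the package ships
its own cohort generator, so none of the claims below depend on access to
whole-slide scans.

## The three-stage pipeline

**Stage 1 — tiling.** Annotated tumour regions (polygons in native pixels,
minus exclusion polygons for folds and debris) are covered by a
deterministic overlapping grid of square tiles at the working resolution.
The published parameters, which are the package defaults in
`pipeline_config()`, are 318 px tiles at 2 µm/px (≈ 5× magnification,
636 µm physical side), 50% overlap (stride 159 px), and retention of a tile
iff at least 50% of its area lies inside the tumour mask ("less than 50%
overlap excluded" implies the retention inequality is inclusive at exactly
one half). The grid is anchored at pixel (0, 0) with no random phase, so
tiling is reproducible; coordinates are 0-based with half-open tile
rectangles, which makes the stride arithmetic unambiguous. Tile-mask
overlap areas are computed exactly in polygon space (a compiled
Sutherland–Hodgman clipping kernel; region booleans use the Clipper
library via `polyclip`), and the test suite checks them against an
independent rasterised pixel-count oracle.

**Stage 2 — tile scorer.** Each retained tile receives a four-class
probability vector. Tiles carry only weak labels — every tile inherits its
slide's transcriptional CMS label, because no tile-level ground truth for
CMS exists. The scorer in this package is a compact single-hidden-layer
neural network (`nnet`) with a softmax head fitted on a per-tile
descriptor: the fractions of spectral energy in eight log-spaced radial
frequency bands of the mean-centred grey tile, the log total spectral
energy, mean RGB and grey-level SD (13 features, `tile_descriptor()`).
The descriptor is invariant to flips and right-angle rotations, so the
standard geometric augmentations are exactly label-preserving in
descriptor space; the photometric augmentations (`augment_patch()`) model
stain and exposure variability. Class imbalance is handled by
inverse-frequency case weights, configurable off in `model_spec()`.

Training proceeds in warm-started rounds; after each round the slide-level
macro-AUROC on the fold's validation patients is recorded and the weights
of the best round are kept (`train_fold()`). This mirrors validation-based
checkpoint selection; the selection metric is slide-level macro-AUROC, the
same metric used for reporting.

**Stage 3 — aggregation and ensembling.** Tile probability vectors are
averaged per slide (unweighted arithmetic mean) and the argmax of the mean
is the slide call (`aggregate_slides()`). Exact argmax ties are broken
towards the lowest class index and flagged explicitly (`tie`), keeping
rare ties auditable rather than silent. Five models are trained on
patient-level five-fold splits stratified jointly by cohort and class
(`make_folds()`): the validation bins partition the development patients,
per-stratum counts per bin differ by at most one, and all slides of one
patient share a bin, so no patient leaks across the split. At case level
the ensemble reports (i) the mean of the five member probability vectors
as its continuous score — this is what ROC analysis consumes — and (ii)
the majority vote of the five member calls as its categorical call; an
undecided vote (any tie for the top count) is called `"mixed"`
(`ensemble_calls()`, `majority_vote()`). Mixed cases keep their score
vector but belong to no one-vs-rest group in the outcome analysis.

## Evaluation

`macro_auroc()` computes one-vs-rest AUROC per class by the rank
(Mann–Whitney) statistic with midrank tie correction, and the macro
average is the unweighted mean over classes present; a class missing
either positives or negatives has undefined AUROC and is excluded with a
warning. The implementation is checked in the tests against an O(n²)
pair-counting oracle and against `pROC`. Confusion matrices
(`confusion_counts()`) include the `mixed` column. The gallery operation
(`top_tiles_gallery()`) reproduces the qualitative-review procedure:
the k highest-scoring tiles for a class under a one-tile-per-patient
constraint, with a deterministic `(patient_id, x, y)` tie-break.

## The virtual-biopsy simulator

The simulator asks how classification performance depends on the number
`m` of biopsy fragments available from a tumour. Its assumptions, stated
as the sampling model: fragment locations are uniform over the tumour
region, fragment shapes are drawn from a library independently of
location, and consecutive fragments do not overlap. One sampling event
(`sample_event()`) draws `m` shapes with replacement, applies a uniform
random rotation and an optional mirror (orientation policy is not dictated
by the sampling model, so it is configurable), translates each to a
uniform point in the mask bounding box, and accepts a placement when at
least 95% of the fragment area lies inside the tumour mask and the
fragment overlaps no previously placed fragment. Strict 100% containment
would make boundary-dominated masks infeasible, so the threshold is a
parameter with default 0.95. Rejection sampling is bounded by
`max_attempts = 1000` per fragment; exhausting the budget raises an
explicit infeasibility error naming the slide and `m`, and the dataset
simulator logs infeasible slides rather than silently dropping events.

Scoring an event applies stage 1–3 with the union of the placed fragments
acting as the annotation mask. Because the tile grid is deterministic,
tile probabilities for the full candidate grid of each slide are computed
once and each event only selects the retained tiles geometrically
(`score_biopsy_samples()`); events retaining no tile (a fragment smaller
than half a tile) are recorded as unscorable and excluded from AUROC with
a logged count. The convergence curve (`convergence_curve()`) reports, per
`m`, the macro-AUROC over all scored events (each labeled with its source
slide's class) per ensemble member, its mean ± SD over members, and the
relative gap to the full-resection reference AUROC. The published
experiment uses 10,000 events per slide (`n_sampling_events` default) over
26 simulated datasets (13 fragment counts × 2 source datasets; the
fragment counts themselves are not printed, so the replication grid
`m = 1..13` is an assumption and fully configurable). The desk-scale
experiment in this package uses `m = 1..8` with 200 events per slide,
which already resolves the convergence plateau on synthetic cohorts.

## Outcome association

`adjusted_or()` fits a maximum-likelihood logistic regression of pCR on
the one-vs-rest group indicator for a subtype plus categorical T-stage,
N-stage and cohort covariates; the subtype odds ratio is the exponentiated
group coefficient with a Wald 95% interval, the convention behind
"OR (95% CI, p)" reporting. T and N stages enter as unordered indicator
variables — the weakest coding assumption, since the published analysis
does not state one. Quasi-complete separation is detected and aborts with
a recommendation to refit with `method = "firth"`, a Jeffreys-prior
penalised fit implemented in the package for sparse strata. With no
covariates the estimator collapses to the closed-form 2×2 odds ratio
(`unadjusted_or()`, Haldane–Anscombe 0.5 correction on zero cells,
flagged). The tests verify parameter recovery on the synthetic outcome
generator: bias of the log-OR below 0.05 at n = 2000 over 200 replicates,
and ≥ 90% CI coverage of a designed OR of 3.

## The synthetic cohort generator

`synth_cohort()` emulates every input the pipeline consumes. Each
resection pseudo-slide is a 1024 px square at 2 µm/px (~2 × 2 mm of
virtual tissue) under an H&E-like two-colour palette. The four classes are
procedural textures — oriented sinusoidal gratings plus Gaussian noise —
that differ in spatial frequency (0.055/0.11/0.18/0.28 cycles per px).
Frequency, not orientation or colour, carries the class signal, so
geometric and photometric augmentations are label-preserving, as for real
tissue. A blobby annotation polygon covers ~60% of the slide; a
`heterogeneity` fraction h of the annotated area (default 0.2, the value
used in all acceptance experiments) is covered by non-overlapping disks of
minority-class texture, emulating intratumoural heterogeneity of
tile-level appearance; h ≥ 0.5 is rejected because the slide label would
no longer be the majority class. Tests verify that the realised
minority-tile fraction tracks h within ±0.05 on average and that a small
scorer separates the four textures with held-out tile-level macro-AUROC
≥ 0.99 — the discriminability gate for all downstream synthetic
experiments. Biopsy-specimen slides are small images holding 2–3
elongated textured fragments with per-fragment annotations.

Fragment shape libraries (`synth_shape_library()`) are smoothly perturbed
ellipses with elongation 1.5–3, stored in local micrometre coordinates;
the default library size of 1580 matches the published pool of annotated
fragment outlines. The default area range, 30,000–70,000 µm² (2–4 tile
areas at the desk-scale working resolution), scales the millimetre-sized
real fragments down to the 2 × 2 mm pseudo-slides so that one fragment
contributes a handful of tiles, as in the published setting where a
fragment spans a small fraction of a resection. Outcome tables
(`synth_outcomes()`) draw pCR from a logistic model with designed
per-class log odds ratios (default: OR 2.69 for CMS1, 0.25 for CMS4,
matching the magnitude of the reported clinical associations) and
categorical stage/cohort effects; the generating truth is attached to the
output for recovery tests.

Pixels are rendered lazily from per-slide seeds, so cohorts of arbitrary
size run in bounded memory, and a fixed master seed makes every
downstream artefact bit-reproducible.

### What the generator does not emulate

Real H&E texture, stain physics, scanner variation, tissue folds, blur,
or endoscopist targeting bias (fragments from the luminal surface are
over-represented in real biopsies; the simulator samples uniformly, as the
published sampling model assumes). Passing the synthetic acceptance
experiments therefore demonstrates correctness of the pipeline mechanics —
tiling arithmetic, leakage-free splitting, aggregation, voting, sampling
geometry, metric computation — and the qualitative convergence behaviour
of biopsy sampling, not clinical-grade discrimination on real slides.

## Numerical and design choices

- **Geometry.** Region construction (tumour minus exclusions, unions)
  uses Clipper via `polyclip` under the even-odd fill rule; hot-path area
  queries use a compiled clipping kernel (rectangle and triangle windows
  after ear-clipping triangulation), cross-checked against `polyclip` and
  a raster oracle in the tests. Degenerate (zero-area) annotation rings
  are dropped with a warning; self-intersecting rings are repaired by
  splitting into simple pieces, and irreparable geometry is an error.
- **Resampling.** Native-to-working downsampling uses block averaging
  over integer factors (e.g. 0.5 → 2 µm/px is 4×), an area-preserving
  anti-aliasing filter; non-integer ratios are an explicit error rather
  than a silent interpolation.
- **Ties.** Slide-call argmax ties break to the lowest class index with a
  flag; ensemble vote ties are the defined "mixed" outcome; AUROC uses
  midranks; gallery ties break lexicographically.
- **Determinism.** All seeded entry points save and restore the caller's
  RNG state, and derived sub-seeds stay within 32-bit integer range. Two
  runs with the same seeds are bit-identical, including trained weights.
- **Problem sizes.** The acceptance experiments use 40 development + 40
  evaluation slides (10 per class), a 200-shape library, `m = 1..8` and
  200 events per slide — sizes at which the convergence plateau and all
  geometric properties are already unambiguous on a single CPU, which is
  the intended desk-scale envelope of this package.
- **Open points resolved here.** Exclusion regions are geometric
  subtractions from tumour polygons; the ensemble's continuous ROC score
  is the mean of member probabilities (vote fractions would discard
  calibration); all scored sampling events are pooled per AUROC rather
  than subsampled; epoch-level hyper-parameters of the published training
  are not claimed — they live in `model_spec()` with CPU-sane defaults.

## Known limitations

The tile scorer is a spectral-descriptor network, not a deep convolutional
network: adequate for the desk-scale textures and for validating every
pipeline contract, but not a drop-in for gigapixel H&E work, where a CNN
backbone behind `predict_tiles()`'s interface would replace it. The
simulator's uniform-location assumption inherits the published model's
acknowledged idealisation of real biopsy sampling. Manual tumour
annotation is consumed as input; automated segmentation is out of scope.
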