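---
title: "Methods: morphology-based APL recognition with smearMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphology-based APL recognition with smearMIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Acute promyelocytic leukemia (APL) is defined by the t(15;17) *PML/RARA*
translocation and must be treated within hours of suspicion, long before
cytogenetic confirmation. The only universally available diagnostic
material at presentation is the Wright-stained peripheral smear, from
which slide-scanning analyzers (CellaVision-class devices) export one
segmented RGB image per white blood cell, typically 200 cells per smear
(user-definable between 100 and 400), each pre-classified into a
morphological type. `smearMIL` asks how much diagnostic signal those
images carry: it learns, from patients whose translocation status is
known, to score cells and whole samples for APL, and then interrogates
what the network used.

# Models and assumptions

## Single-cell classifier

Images are resized to 360 × 360 pixels by bilinear interpolation
(half-pixel-center convention, pinned in `src/imageops.cpp` so tests can
check it against an independent reference) and scaled into [0,1]. The
network is four convolutional layers (16/32/64/128 filters, 3 × 3
kernels, stride 2, ReLU, no padding), a global max-pool over spatial
positions, three fully connected ReLU layers (32/22/11) and a 3-class
softmax. Two architectural facts matter downstream:

* global max-pooling makes the network input-size agnostic and gives
  translational invariance — exactly so for translations that are
  multiples of the aggregate stride (16 px), only approximately
  otherwise, because stride-2 valid convolutions change sampling phase
  under sub-stride shifts. The test suite asserts the exact
  stride-multiple case; sub-stride deviations on sharp synthetic cells
  can be large and users should not expect pixel-level shift equivariance;
* the last four layers (32 + 22 + 11 + 3 softmax) concatenate to a
  68-dimensional per-model latent feature vector; across a 100-model
  ensemble this gives the 6800-dimensional space used for visualization.
  Reading "last four layers" as the three fully connected activations
  plus the softmax is a design choice: it is the reading consistent with
  the 68-dimensional latent space given the classification layer has 3
  units.

Unspecified details of the original architecture (kernel sizes, filter
counts, activations, optimizer) are filled with standard choices:
He-initialized weights, Adam, default learning rate `1e-4`, batch 32.
The worked examples and the test suite run small synthetic cohorts with
`lr = 1e-3` and small epoch caps purely so they finish in seconds to
minutes; the defaults are what we would use at full scale.

## The blurred outgroup

Stain color drifts with smear age, and collection era can be confounded
with diagnosis (in the motivating data, every smear collected before
2018 was an APL smear). Rather than normalizing color, training adds a
third class: a Gaussian-blurred copy of **every training image** (so the
outgroup size equals the training-set size). The blur (default sigma 11
px at 360 px, scaled linearly for smaller images, kernel truncated at
4σ) destroys morphology but preserves global color, so color alone can
no longer identify a real class against its blurred twin and the model
is pushed toward morphology.

Two leakage rules are fixed: the outgroup is rebuilt per Monte-Carlo
repetition from that repetition's training images only (held-out
patients never contribute outgroup members), and blurring happens after
resizing (the blur SD is defined on the model's pixel grid).

A caveat that our synthetic experiments make explicit: with a fully
separable, binary-era color shift, the three-class objective still
admits an optimum that uses color conditionally on sharpness, so the
outgroup's protection is a training-dynamics effect rather than an
identifiability guarantee. The package exposes both arms
(`trainCellClassifier(..., outgroup = FALSE)` is the two-class control)
and the acceptance suite measures the paired contrast on era-randomized
test cohorts.

## Multiple-instance (sample) classifier

Diagnosis labels attach to the patient. The MIL model applies the same
per-cell network to the bag of a patient's cells and averages the
per-cell softmax assignments **inside the network**; the bag-level
cross-entropy trains it. Per-cell predictions are read from the
assignment layer in the middle of the network. Each training bag
contributes a blurred twin labeled with the outgroup class. Each epoch
draws 25 random cells per bag (all cells when the bag is smaller), which
keeps epochs cheap while touching all data across epochs. Because there
are far fewer samples than cells, no validation half is reserved in MIL
mode (75/25 train/test); training stops at a fixed mean training loss
(default 0.2, hard cap 300 epochs with a warning).

The aggregation identity — bag probability equals the componentwise mean
of per-cell probabilities within 1e-6 — is asserted for bags of 1 to 400
cells, and the binary sample score renormalizes the bag triple over the
two real classes, `P(APL) = p_apl / (p_apl + p_nonapl)`; the blurred
class is a training device, not a diagnosis. A degenerate all-blurred
triple returns 0.5 with a warning.

## Monte-Carlo cross-validation and ensembling

Each repetition draws a patient-level split — never cell-level, so no
patient's cells straddle train and test — stratified by class so both
labels are always trainable: 75% train, and for the cell model the
remaining 25% is halved into validation (early stopping, patience 5,
minimum improvement 1e-3 in validation cross-entropy) and test. Out-of-
fold predictions pool across repetitions into the discovery report; the
ensemble of all repetition models scores held-out cohorts by unweighted
mean. The full-scale protocol uses 100 repetitions; the test suite runs
a complete 100-repetition pass at miniature problem size to audit
membership and split hygiene, and 2–5 repetitions where real training
quality matters.

ROC AUC is computed rank-based (Mann-Whitney, ties counted one half) and
cross-checked against exhaustive concordant-pair counting and against
`pROC`. The comparator biomarker is the promyelocyte fraction of the
sample, a quantity the analyzer provides at admission. The evaluation
report also stratifies per-sample AUC by cells-per-patient quartiles
(observational; low-cell samples are expected to be harder, and no
monotonicity is asserted).

## Integrated gradients

Attribution maps use integrated gradients with the **blurred image as
baseline** — the natural reference here, since the baseline keeps stain
context and removes morphology, making the attribution "what sharp
morphology adds". The path is 100 scaled images from baseline to input;
gradients of ΔP = P(APL) − P(non-APL) are averaged with a left-Riemann
rule at path points k/steps (k = 0..steps−1), multiplied by
(input − baseline), and summed over RGB channels for display. The
completeness axiom (attributions sum to ΔP(input) − ΔP(baseline)) is
tested with the discretization error decaying as the step count doubles,
and a linear surrogate model checks the closed form exactly. Consensus
maps average 25 uniformly sampled (seeded, without replacement) ensemble
members. Overlays normalize the map to [−1, 1] by its maximum absolute
value and alpha-blend (0.5) a diverging blue-white-red colormap over the
original image.

## Latent-space visualization

For cells of a held-out cohort, the 68 last-four-layer features are
extracted from every MIL ensemble member and concatenated in ensemble
order. Features are standardized per dimension (zero mean, unit
variance; constant dimensions left untouched) before PCA — the layers
live on heterogeneous scales and would otherwise dominate each other —
and the minimal number of principal components reaching ≥ 99% cumulative
explained variance is kept. A 2-D UMAP of the retained scores (15
neighbors, `min_dist` 0.1, 200 epochs) is computed with a fixed seed.
Because no UMAP implementation is available in the package's R
dependency set, `umapEmbed()` is a compact implementation authored here:
exact k-nearest-neighbor graph, smoothed-kNN bandwidth calibration
(per-point sigma solving the log2(k) constraint), fuzzy-union
symmetrization, the standard low-dimensional curve fit for (a, b) from
`min_dist`, deterministic PCA initialization scaled to [−10, 10], and
negative-sampling SGD with the epochs-per-sample schedule and its own
seeded xorshift stream, so embeddings are bit-reproducible. Class-
conditional Gaussian kernel densities (`MASS::kde2d`) are estimated on a
common grid in the embedding.

# The synthetic cohort generator

The generator exists so the whole pipeline is buildable and testable
without the clinical download. It emulates exactly the features the
method exercises:

* **Chromatin regime (the planted class effect).** Within the nucleus,
  chromatin density follows a radial gradient controlled by
  `chromatin_centrality` ∈ [0,1]: APL immature myeloid cells default to
  0.85 (condensed, centrally concentrated — rendering darker nucleus
  centers), non-APL to 0.15 (dispersed, peripheral). Mature cell types
  always render at neutral 0.5, confining the class signal to the
  immature compartment. APL cells also carry heavier cytoplasmic
  granulation (3 vs 1.2 granules per 1000 px²).
* **Cell-type mixtures.** APL smears draw 40% promyelocytes and fewer
  monocytoid cells; non-APL smears draw more blasts, promonocytes and
  monocytes. Counts per patient default to 200.
* **Batch confound.** Patients are assigned to a collection era;
  confounded-era patients get a constant additive RGB stain shift
  (default (28, −14, 18) on 0–255). `class_correlation` is the
  probability an APL patient lands in the confounded era (1 reproduces a
  fully one-sided confound; setting the non-APL era probability to 0.5
  as well gives era assignment independent of class, the "deconfounded"
  regime used for evaluation).
* **Determinism.** Geometry is a pure function of (cell type, morphology
  parameters, image size); only granule placement and pixel noise draw
  random numbers, and per-cell variability comes from seeded jitter of
  the morphology parameters in `simulateCohort()`. Identical
  configurations therefore produce byte-identical datasets.

Effect sizes are chosen for testability — the source study does not
quantify its real morphological effect sizes — and the defaults make the
planted signal strong: a 5-repetition Monte-Carlo run on a 10 + 10
patient, 100-cell, 64-px cohort recovers it with out-of-fold AUC above
0.9 (in practice 1.0). What passing these tests shows is that the
pipeline's plumbing — splits, outgroup, aggregation, ensembling, ROC —
is correct and that the planted morphology is recoverable; it says
nothing about performance on real smears, where effects are weaker,
stains overlap continuously, segmentation is imperfect and cell-type
labels are noisy. The renderer makes no attempt at photorealistic Wright
staining or red-cell characterization.

# Numerical choices and degenerate inputs

* Preprocessing divides by 255 only when the input exceeds 1, so it is
  idempotent on already-normalized tensors; resize and blur conventions
  are pinned in compiled code and tested against independent references.
* Minimum input size is 31 px (four stride-2 valid 3 × 3 convolutions);
  smaller inputs raise an informative error. Tests use 32–64 px images,
  the full-scale contract is 360 px.
* `rocAuc` refuses single-class inputs; report assembly converts that
  into `NA` rather than failing a whole run.
* Ranking of most-predictive cells averages per-cell scores across
  repetitions first and breaks ties lexicographically by (patient, path),
  so figure panels are deterministic.
* Empty bags after scope filtering are dropped from training with a
  warning and skipped in evaluation with a warning; a training split
  missing a class raises an error.
* All run-level randomness derives from integer seeds; per-repetition
  substreams are derived arithmetically (kept below 2³¹). Training and
  inference are single-threaded and deterministic given the seed.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run, as this package's own
choice of demonstration scale: 32–64 px images; cohorts of 6–20 patients
with 100 cells each; 1–5 training repetitions (plus one complete
100-repetition miniature pass for ensemble/split audits); 2-repetition
MIL runs. The full-scale protocol (360 px, 100 repetitions, 200 cells)
is the same code with larger arguments.

# Known limitations

* The synthetic generator is a falsifiable fixture, not a simulator of
  Wright-stain photochemistry; conclusions about real data require the
  clinical images.
* With a fully separable synthetic confound the blur outgroup does not
  provably remove color reliance (see above); its benefit is empirical.
* Sub-stride translation equivariance does not hold exactly for the
  stride-2 architecture.
* The MIL loss threshold stopping rule is a free parameter; when the
  threshold is unreachable the run stops at the epoch cap with a
  warning rather than failing.
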