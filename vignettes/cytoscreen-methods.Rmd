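---
title: "cytoscreen: models, design choices and what the synthetic benchmarks show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytoscreen: models, design choices and what the synthetic benchmarks show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoscreen)
```

## The screening problem

Cervical cytology screening reads liquid-based (ThinPrep/TCT) slides for
abnormal squamous cells. `cytoscreen` implements a two-stage pipeline over
single-field microscope images:

1. **Cell stage** — detect every cell nucleus in a field, segment its
   contour, and classify it as `yin` (normal), `yin-yang`
   (suspected/ecological) or `yang` (diseased). The cytologic criteria are
   morphological: lesion severity correlates with nuclear enlargement,
   darker haematoxylin staining, higher nucleocytoplasmic (N/C) ratio and
   increasingly irregular nuclear contours.
2. **Patient stage** — aggregate the per-patient cell counts into seven
   features (age; the three class counts; `yang_ratio`; `combined_yang =
   yin_yang + yang`; `combined_yang_ratio`) and classify the patient as
   normal vs. positive with logistic regression, a random forest, an RBF
   SVM and gradient-boosted trees under stratified 10-fold
   cross-validation.

Around the two stages the package provides the *pre-label-and-revise*
active-learning annotation protocol, a seeded synthetic data generator so
every component is testable without any image download, and a complete
evaluation kit.

## The synthetic field generator

No public imaging data accompany this problem at desk scale, so
`generate_field()` draws its own: nuclei are radial-Fourier-perturbed
ellipses (harmonics 2–5, amplitudes scaled by a per-class `irregularity`
parameter) painted over a pale cytoplasm-toned background, each inside a
circular cytoplasm halo whose radius is `nucleus_radius / sqrt(ncr)` so
the N/C-ratio proxy is visible in the rendering. Default class morphology
(all units: pixels and the 0–255 stain-darkness scale):

| class    | radius mean ± sd | intensity mean ± sd | irregularity | N/C proxy |
|----------|------------------|---------------------|--------------|-----------|
| yin      | 9 ± 1.2          | 150 ± 12            | 0.05         | 0.25      |
| yin-yang | 13 ± 1.5         | 100 ± 12            | 0.15         | 0.45      |
| yang     | 18 ± 2.0         | 60 ± 12             | 0.40         | 0.70      |

These defaults deliberately produce *well-separated* classes in
(radius, intensity) space: the generator's job is to provide a regime in
which a correct pipeline must succeed, not to imitate scanner photometry.
Consequences to keep in mind:

* Passing benchmarks on these fields shows the pipeline's machinery is
  correct (segmentation, matching, losses, aggregation, bookkeeping). It
  does **not** show that the classical reference detector would reach
  comparable accuracy on real stained slides, where class-conditional
  distributions overlap heavily and imaging artifacts dominate.
* Features *not* emulated: overlapping/adherent cells (fields are packed
  by rejection until pairwise bounding-disc IoU is at most
  `overlap_fraction`, default 0 — mirroring the practice of selecting
  fields with few overlapping cells), out-of-focus regions, stain batch
  variation, debris, and cytoplasm segmentation (only nuclei carry ground
  truth, as in nucleus-level annotation workflows).

Fields default to 256×256 px for desk-scale runtime; 1024×1024 scanner
resolution is one `field_size` argument away. All randomness flows from a
single integer seed through `derive_seed()`, a splittable counter-style
hash, so every artifact is bit-reproducible (`same seed ⇒ identical PNG
bytes`).

Patient cohorts (`generate_cohort()`) default to 400 patients at
prevalence 211/400 with 3 fields × 200 cells per patient. Positive
patients carry yang cells at rate 0.01 per cell — the dense end of the
1:100–1:1000 abnormal-to-normal imbalance typical of cytology — and
negative patients carry none. The yin-yang ("suspected") rate is equal in
both groups (0.01) so that, by design, the outcome is driven by the yang
signal alone; this is the generative condition the patient-stage
parameter-recovery benchmark tests (tree importances should then
concentrate on `yang` and `yang_ratio`). `label_noise` flips each
recorded clinical label independently (default 0; the benchmark uses
0.02), emulating diagnostic error and capping attainable accuracy near
`1 - noise`. ~3000 fields per patient, as a scanner would produce, would
change nothing statistically at these rates, only runtime; the field
count is configuration.

## Geometry conventions

Coordinates are 0-based, x rightward, y downward; polygon vertices live at
pixel-corner resolution and the pixel at column `cx`, row `cy` has center
`(cx + 0.5, cy + 0.5)`. `polygon_to_mask()` sets exactly those pixels
whose centers fall inside the polygon under the even-odd rule — an
unambiguous convention that the test suite verifies against a brute-force
per-pixel point-in-polygon oracle. `mask_to_polygon()` traces the
boundary between inside and outside pixels along pixel corners, so
rasterizing the traced polygon recovers the mask exactly for connected
hole-free masks (diagonally-kissing corners are resolved by turning toward
the interior); detection polygons therefore rasterize back to their
segmentation masks with no quantization loss.

## The reference detector

GPU instance-segmentation backbones are out of scope; the package instead
defines a backend-agnostic contract (`train_detector()` / `detect()` /
`save_detector()` / `load_detector()`) and ships one classical reference
backend:

1. **Candidate segmentation** — Otsu threshold on inverted luminance
   (stained nuclei are dark), then a distance-transform watershed
   (`ws_tolerance = 3`) to split touching blobs; blobs smaller than
   `min_area = 20` px or brighter than `max_lum = 0.8` mean luminance are
   discarded, which also keeps blank fields detection-free.
2. **Features** — area, equivalent diameter, mean/min luminance,
   moment eccentricity, convex-hull solidity, boundary roughness
   (`perimeter² / 4πA` on the rectilinear perimeter) and the radial
   coefficient of variation.
3. **Classification head** — a multinomial logistic model
   (`nnet::multinom`) on standardized features, with per-case weights
   from `compute_class_weights()` — inverse class frequency, normalized
   to 1 at the majority class and capped (default 100) — so the fitted
   objective is exactly the class-weighted cross-entropy loss the package
   also exposes standalone. A small L2 decay (`1e-3`) keeps the
   probabilities calibrated when the training classes are linearly
   separable; without it the softmax saturates and single atypical nuclei
   can be called with unwarranted certainty.
4. **Output** — each blob's traced polygon, full class-probability
   vector, and `score = max(prob)`, filtered by score-descending NMS at
   IoU 0.5 (ties broken by lower index), the same threshold the
   evaluation uses.

Training images with any abnormal cell can be replicated to a target
fraction (`oversample_positives()`, default target 0.25) before feature
harvesting, and the three-way augmentation (`augment()`) can double the
training set. Warm starting (`init =`) passes the previous round's
multinom weights to the optimizer, which is how active-learning rounds
"train based on the previous model".

The loss components of the detection framework this mirrors are exposed
as standalone, unit-verified functions: `rpn_loss()` (binary objectness
cross-entropy plus smooth-L1 box regression gated to positive anchors,
normalized by `N_cls` = anchor count and `N_reg` = positive count with
balance weight λ = 1 by default — conventional normalizations, since no
canonical values exist), `classification_loss()` (the ω-weighted
cross-entropy, ε = 1e-12 inside the log), `mask_bce()` and
`total_loss()`. λ and the ω values are design defaults, not published
constants.

## The annotation protocols

`run_conventional()` labels every non-test image fully manually and
trains once (model T1). `run_active()` follows the three-iteration
pre-label-and-revise design — batch sizes default to 100/200/150 with a
fixed 50-image test set; the desk-scale benchmarks run the same
proportions at 60 images (15/20/15, test 10) purely for runtime — where
round 1 is manual and each later round pre-labels its batch with the
previous model and passes it to a simulated pathologist.

The revision oracle (`simulate_revision()`) matches pre-labels to truth
(greedy, IoU ≥ 0.5, score-descending) and then: accepts correct-class
matches at zero cost (snapping to the truth contour); corrects wrong-class
matches with probability `revision_fidelity` at one `cost_fix`; draws in
missed nuclei with probability `miss_add_rate` at one `cost_draw`; deletes
spurious pre-labels with probability `revision_fidelity` at one
`cost_fix`. Wall-clock labeling hours are not reproducible, so the cost
ledger is a click-count proxy: drawing a polygon from scratch costs 5
units, fixing a label or deleting a contour costs 1 (configurable). With
`revision_fidelity = 1` and `miss_add_rate = 1` the revised labels equal
ground truth exactly — the *perfect-oracle equivalence limit*, under which
the cumulative active-learning training set is identical to the
conventional one and the two final models should agree up to optimizer
path; the acceptance suite checks exactly this, plus the strict cost
ordering whenever pre-label accuracy is positive.

Whether later rounds should retrain on all revised data or only the
newest batch is genuinely open; the default is cumulative (consistent
with monotonically improving loss curves), with `cumulative = FALSE`
available. Batch membership, the test split and every oracle draw are
seeded; batches and the test set are pairwise disjoint by construction.

## Evaluation machinery

* `match_detections()` — greedy one-to-one matching in descending score
  at IoU ≥ 0.5, producing the 3-truth-class × (3 predicted + *missing*)
  confusion matrix; detections matching nothing are tallied separately as
  spurious and never enter the matrix.
* `binary_metrics()` — collapses that matrix for a chosen positive set
  under the *missing-as-predicted-negative* policy: a missed positive
  cell is a false negative, a missed negative cell a true negative. This
  single convention reproduces, to two decimals, all per-class yin
  sensitivities/accuracies and all composite (yin-yang + yang) columns of
  the published cell-classification table from the published confusion
  matrices. The per-class yin *specificity* entries printed alongside
  (69.95 / 66.37) are not derivable from those matrices under any
  standard convention we tried; the package reports the
  convention-consistent value and leaves the discrepancy documented here
  rather than matching it.
* `pr_curve_auc()` — thresholds swept over unique scores descending, AUC
  by the uninterpolated rectangle rule `Σ (R_n − R_{n−1}) P_n` (no VOC
  11-point interpolation), verified against exhaustive threshold
  enumeration; `average_precision()` fixes the recall denominator at the
  ground-truth count so detection AP penalizes misses.
* `map_mar()` — per-class AP/AR at IoU 0.5, unweighted class means,
  spurious detections counting as false positives; classes without truth
  are excluded with a warning.
* `f1_gmean()` — F1 and the geometric mean of recall and specificity
  (with the square root, the standard definition; F1 of an empty
  prediction set is defined as 0 and flagged).
* `friedman_compare()` / `wilcoxon_pairwise()` — methods × folds
  comparisons. Mean ranks are reported with 1 = best. The signed-rank
  p-value is exact for up to 25 pairs via a generating-function
  convolution over doubled mid-ranks — equivalent to enumerating all 2^n
  sign patterns, and still exact under tied ranks, where off-the-shelf
  exact routines fall back to approximation — with Holm adjustment
  across pairs.

## Numerical and degenerate-input choices

Probabilities are clamped at 1e-12 inside logs (with a warning when the
clamp engages on a true class). Zero-denominator metrics return `NA` plus
an `undefined` flag instead of erroring. `N_reg` defaults to
`max(1, #positive anchors)` so an all-negative anchor batch has a
well-defined zero regression term; passing 0 explicitly errors. Fields
too small for the requested nuclei raise an explicit packing-failure
error after 300·n placement attempts. Degenerate single-class training
sets fit a constant-class model with a warning. Class strings are
normalized case-insensitively onto the three canonical names.

## Benchmark problem sizes

The test and acceptance suites run: 30/10-field train/test fixtures with
30 nuclei per 256×256 field for the detector; 60-field protocol runs
(15/20/15, test 10) over 5 seeds for the protocol-equivalence benchmark;
a 400-patient cohort (prevalence 211/400, 2% label noise) for
patient-stage parameter recovery; and ≥100 random instances (n ≤ 50) for
each statistical oracle. These sizes are the package's desk-scale
choices; every size is a parameter, and the full-scale 500/50 design
remains the default of `protocol_config()`.

## Known limitations

* The reference detector is a deliberately classical stand-in behind the
  backend interface: adequate on separable synthetic morphology,
  not competitive on real slides; a deep backend can be slotted in
  without touching any other module.
* Cytologic subtype grading (ASCUS/LSIL/HSIL), HPV status and other
  clinical covariates, and real WSI/scanner ingestion are out of scope.
* PR-AUC and mAP here are single-IoU (0.5) quantities; no 0.5:0.95
  averaging.
* The simulated pathologist is an invented, parameterized stand-in for
  human revision; its cost ledger supports *relative* protocol
  comparisons, not absolute labeling-time claims.
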