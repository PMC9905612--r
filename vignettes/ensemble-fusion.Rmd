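---
title: "Confidence-weighted ensemble fusion for leukocyte detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted ensemble fusion for leukocyte detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leukofuse)
```

## The problem

Automated detection of the five peripheral-blood leukocyte types —
neutrophil (NG), basophil (BG), eosinophil (EG), lymphocyte (L) and
monocyte (M) — on stained smear images is usually done with a single deep
detector. Individual detectors make partly independent mistakes: missed
cells, spurious boxes on impurities, wrong class under poor staining.
`leukofuse` implements a detector-agnostic ensemble that combines the
bounding-box outputs of `M` trained detectors into one prediction set, plus
the full evaluation stack needed to quantify whether the ensemble helps.

The package never touches pixels. Its inputs are detection lists (box,
confidence, class, source model) and ground-truth annotations; its outputs
are fused detection lists and metric reports.

## The fusion model

For each image, detections from all models are pooled and grouped into
clusters of mutually overlapping boxes. Within a cluster of `N` members with
corner vectors $L^i = [x_1^i, y_1^i, x_2^i, y_2^i]$ and confidences $C^i$:

1. **Support rule.** A cluster is kept only if $N \ge M/2$ — a candidate
   object endorsed by fewer than half the detectors is treated as a false
   positive and discarded (the discarded members are returned, not silently
   dropped).
2. **Majority vote.** The fused class is the most frequent member label;
   $T$ denotes its count. Ties go to the label with the larger summed
   confidence, then to canonical class index, and are flagged.
3. **Box average.** The fused box is the confidence-weighted mean
   $L' = \sum_i C^i L^i \,/\, \sum_i C^i$: a more confident detector pulls
   the fused box toward its own localization.
4. **Confidence update.** $C' = \sum_i C^i / D$. With `divisor = "models"`
   (the default) $D = M$: detectors that emitted nothing for the region act
   as abstentions and lower $C'$, which also guarantees $C' \le 1$ whenever
   each model contributes at most one member. With `divisor = "majority"`,
   $D = T$; this variant can exceed 1 when minority-label confidences enter
   the numerator, and the value is reported as computed rather than clipped,
   so the user sees the semantics they selected.

Both divisor semantics are deliberately exposed because the two published
descriptions of this update (a formula normalising by the majority count,
and prose describing an average over all models) disagree; the model-count
form is the default since only it realizes the stated abstention-penalty
behaviour.

### Clustering procedure

"Overlapping" needs a numeric definition and a deterministic procedure;
we use greedy clustering in the style of weighted-boxes fusion:

- Detections are processed in descending confidence (ties: model id, then
  input order — determinism matters more than the specific tie order).
- A detection joins the first cluster whose *running confidence-weighted
  mean box* it overlaps with IoU ≥ `cluster_iou` (default **0.55**, the
  weighted-boxes-fusion convention) and which has no member from the same
  model; otherwise it seeds a new cluster.
- One member per model per cluster: `T` and the `N ≥ M/2` rule count
  *models*, which presumes per-model uniqueness; a model's second box on the
  same object seeds its own (usually discarded) cluster.

Boxes are continuous, zero-based corner coordinates with area
$(x_2-x_1)(y_2-y_1)$ and no +1 pixel correction — the weighted average
produces fractional corners, and the +1 convention would break the scale
invariance of both IoU and the fusion equations. Zero-area boxes are
rejected at ingestion: they poison IoU and the fusion weights.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cluster_iou` | 0.55 | IoU (dimensionless, 0–1) for joining a cluster |
| `min_support` | 0.5 | keep a cluster iff `N ≥ min_support · M` (boundary kept) |
| `divisor` | `"models"` | denominator of `C'`: model count vs majority count |
| `scope` | `"all_members"` | whether minority-label boxes enter the box average |
| `tie_break` | `"summed_confidence"` | majority-tie resolution |

`scope = "all_members"` is the default because the summation in the fused-box
formula runs over all `N` members; `majority_only` is provided for users who
prefer label-consistent averaging. The confidence numerator always sums all
members.

## Evaluation protocol

Matching is greedy in descending confidence: a detection matches the
unmatched ground truth (same class, when class-aware) of highest IoU at or
above the threshold; IoU ties go to the lower ground-truth index. On top of
this the package computes:

- **AP** per class and IoU threshold with **101-point interpolation**
  (mean over the recall grid 0.00–1.00 of the running-max precision), the
  COCO convention — chosen because the headline metrics are reported in the
  mAP@IoU=0.50:0.95 style, not 11-point VOC.
- **mAP / mAR** averaged over the ten thresholds 0.50–0.95 and over classes
  *that have ground truths*; a class absent from the test set yields `NA`
  and is excluded from the mean rather than counted as 0 — with only a
  handful of basophils in a typical test split this choice visibly matters.
  mAR uses up to 100 top-confidence detections per image and class (the COCO
  default; the convention is stated because published tables rarely say).
- **Confusion matrix** (5 classes + background) built from *class-agnostic*
  matching — otherwise cross-class cells (an NG detected as M) could never
  be populated.
- **Tagged accuracy**: over ground truths carrying an interference-factor
  tag, the fraction matched by a correct-class detection at IoU ≥ 0.5. The
  percentages published for such subset analyses never come with an
  operational definition; ours is declared, not inferred, and should not be
  compared digit-for-digit with any specific publication.

## The synthetic benchmark

The simulator emulates the structure of a multi-cell blood-smear detection
dataset so fusion and evaluation can be tested end to end without images:

- **Scenes**: 600×600 canvas (the "mini" working resolution of such
  datasets); class frequencies default to the composition of the target
  dataset, NG:BG:EG:L:M = 4135:300:1100:1879:1181; cells per image default
  to 1/2/3 with probabilities 0.65/0.25/0.10 (mean ≈ 1.45, about a third of
  images multi-cell, matching a dataset of ~8.6k cells over ~6.3k images);
  placed boxes never exceed pairwise IoU 0.3 (distinct leukocytes touch but
  do not coincide); an 80/20 train/test split (ratio 4:1) is recorded.
- **Tags**: interference factors are modeled as *condition labels with
  noise multipliers*, not image effects — stain/pH tags inflate the
  class-confusion mass, overlap tags the miss rate, impurity tags the
  false-positive rate. Per-factor prevalences are free parameters (no
  per-factor counts are available in the main text of the literature this
  emulates); the defaults (4–7% per factor) were fixed once as plausible
  clinical frequencies and are not calibrated to any dataset.
- **Detectors**: each profile has a miss probability, a Poisson
  false-positive rate per image, corner jitter proportional to box size, a
  row-stochastic 5×5 confusion matrix, and the confidence model
  `clamp(base − slope·(1 − IoU(jittered, true)) + noise, floor, 1)`. The
  monotone link between localization quality and confidence is the minimal
  assumption that makes confidence-weighted averaging meaningful; real
  detector scores are less well behaved (calibration drift across
  architectures, confidence plateaus), so passing tests here demonstrate
  the pipeline's correctness, not transferability of any specific metric
  value to real smears.
- **Reproducibility**: R's Mersenne-Twister with an explicit integer seed;
  every bundle is a pure function of (configuration, seed) and records the
  seed in its manifest.

What the simulator does *not* model: pixel appearance, correlated errors
between detectors sharing a backbone, confidence miscalibration, annotation
noise. Ensemble gains measured on it are therefore optimistic — independent
per-model noise is exactly the regime where majority filtering and
averaging shine.

## Numerical and degenerate-input choices

- All fusion and evaluation paths are deterministic; ties are broken by
  documented, ordered rules, never by hash or pointer order.
- Weighted means keep fused corners inside the members' min/max envelope up
  to floating-point roundoff (~1e-14); property tests use a 1e-9 guard.
- All-zero confidence clusters raise an error (undefined weights) instead
  of returning NaN boxes.
- Readers reject malformed records (zero-area boxes, dangling image ids,
  unknown categories, scores outside [0,1]) with the offending record named;
  nothing is repaired silently. VOC's 1-based inclusive integer corners are
  converted by subtracting 1 from the min corner on read, and round trips
  are exact up to the documented 1-pixel shift.
- Scene generation retries infeasible placements a bounded number of times
  (200 per cell) and then fails loudly.

## Problem sizes used in the shipped checks

The test-suite and the reproduction script run at desk scale: 200 random
fusion instances of ≤ 12 boxes against a straight-line reference
implementation; 50 random evaluation instances against an independently
coded 101-point evaluator (agreement within 1e-6); a 300-scene, six-detector
benchmark (miss 0.1, 0.5 FPs/image, 5% jitter, 5% confusion) for the
ensemble-benefit comparison; and 10,000 single-cell scenes for exact
binomial/multinomial calibration of the simulator (99% acceptance regions).
These sizes give stable verdicts for every property tested while keeping a
full run in the low minutes.

## Known limitations

- The greedy, confidence-ordered clustering is order-dependent by design;
  pathological geometries (chains of partially overlapping boxes) can split
  or merge differently than a globally optimal clustering would.
- Fused confidences in `majority` mode are not probabilities and can exceed
  1; downstream consumers that require [0,1] scores should use `models`
  mode (the CLI's COCO writer caps at 1 for format compliance).
- The evaluator assumes axis-aligned boxes and single-label ground truth;
  crowd regions, masks and rotated boxes are out of scope.
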