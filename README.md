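# leukofuse

Ensemble fusion and evaluation for leukocyte detection in blood-smear
images.

Single deep detectors for the five white-cell types — neutrophil (NG),
basophil (BG), eosinophil (EG), lymphocyte (L), monocyte (M) — make partly
independent mistakes: missed cells, boxes on impurities, wrong classes
under poor staining or pH drift. `leukofuse` combines the bounding-box
outputs of `M` detectors into one more robust prediction set, and ships the
full metric stack needed to show whether the combination helps. It works
purely on detection lists and annotations (COCO JSON, Pascal VOC XML) —
no images, no trained networks required.

## The method

Per image, detections from all models are greedily clustered by IoU
(threshold 0.55) against each cluster's running weighted-mean box, at most
one member per model per cluster. For a cluster of `N` members with boxes
`L^i` and confidences `C^i`:

- **discard** the cluster if `N < M/2` (fewer than half the detectors
  endorse the object);
- **vote** the class label: the majority label among members wins (`T` =
  majority count; ties resolved by summed confidence, then class index);
- **fuse** the box as the confidence-weighted mean
  `L' = Σ C^i·L^i / Σ C^i`;
- **update** the confidence as `C' = Σ C^i / M` (default), so detectors
  that stayed silent lower the score like abstaining experts; the literal
  majority-count divisor `C' = Σ C^i / T` is available as
  `divisor = "majority"`.

Evaluation follows the COCO conventions: 101-point interpolated AP, mAP and
mAR averaged over IoU 0.50:0.95, per-class AP, PR curves, a 6×6 confusion
matrix with a background class, and accuracy conditioned on
interference-factor tags (over-staining, pH, overlapping cells, impurities,
incomplete cells, ...). A seeded synthetic benchmark generator emulates
multi-cell smear scenes and noisy detectors so every stage is testable.

## Worked example

Simulate six noisy detectors on 60 scenes, fuse, and evaluate:

```r
library(leukofuse)

profiles <- lapply(1:6, function(i) detector_profile())   # miss 0.1, 0.5 FP/img, 5% jitter
bench    <- generate_benchmark(scene_config(), profiles, n_images = 60, seed = 7)

pooled <- do.call(rbind, bench$detections)
res    <- ensemble_fuse(pooled, n_models = 6)
nrow(pooled); nrow(res$fused); nrow(res$discarded)
#> 660 detections in, 87 fused out, 188 discarded as under-supported

head(res$fused, 3)
#>   image_id       x1         y1       x2        y2 confidence label support majority
#> 1        1 475.2729 456.370478 597.4771 553.40656  0.7262449     L       6        6
#> 2        1  90.5723 119.347698 172.8184 197.17733  0.6052073    BG       5        5
#> 3        1 279.8692   6.121626 382.8435  94.73905  0.5002797    NG       4        3

evaluate_detections(transform(res$fused, model_id = "ensemble"), bench$gts)
#> Detection evaluation report
#>   mAP@0.50:0.95 0.9157 | mAP@0.50 1.0000 | mAP@0.75 1.0000 | mAR 0.9328
#>   per-class AP: NG=0.9281 BG=0.9168 EG=0.9139 L=0.9199 M=0.8999
#>   tag accuracy: high_ph=1.0000 impurity=1.0000 incomplete=1.0000 low_ph=1.0000 overlapping=1.0000

mean_ar(bench$detections$m1, bench$gts)$mAR   # one detector alone
#> 0.6067
```

Reading the numbers: each fused row reports its `support` (`N`, how many
detectors boxed the object) and `majority` (`T`, how many agreed on the
class). The ensemble recovers 93% of cells averaged over the strict IoU
grid while a single simulated detector manages 61% — the fused boxes are
more accurate (weighted averaging cancels independent jitter), so they
survive the high-IoU thresholds that dominate mAR@0.50:0.95, and the
`N ≥ M/2` rule removes the unsupported false positives that would otherwise
cap precision.

A thin CLI over the same functions lives at `inst/cli/leukofuse`
(`fuse`, `evaluate`, `simulate` subcommands).

## Documentation

The methods vignette (`vignettes/ensemble-fusion.Rmd`) describes the fusion
model and its assumptions, the evaluation conventions, what the simulator
does and does not emulate, and the package's numerical and degenerate-input
policies.
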