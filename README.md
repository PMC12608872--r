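# sealscope

Toolkit for **hierarchical dual-model UAV surveys of spotted seals
(*Phoca largha*)**: a lightweight detector screens frames onboard the drone,
a high-precision detector verifies the transmitted frames at the ground
station, and per-frame counts are reconciled into a survey total. The
package is aimed at ecologists and engineers building or auditing such
survey systems who need the architecture sizes, the evaluation arithmetic
and the pipeline logic to be exact and testable — without access to
restricted field imagery.

## What is inside

**Detector graphs with exact size accounting.** Declarative model graphs for
both families — the NMS-free onboard baseline (`build_yolov10n()`), its
lightened variants `build_f_yolov10()` (every C2f stage rebuilt with
FasterNet bottlenecks: a partial convolution over a 1/4 channel prefix, a
2× pointwise expansion, a bias-free pointwise projection, residual) and
`build_ff_yolov10()` (additionally, focal modulation in place of the
spatial-pyramid tail: an L = 2 depthwise context pyramid with kernels 3 and
5, scalar per-location gates, multiplicative query modulation) — and the
ground-station family (`build_yolov7()`, plus `build_yolov7_a()` with a
fourth stride-4 small-target scale and `build_pp_yolov7()` with the
partial-convolution ELAN-branch substitution). `count_parameters()` counts
every stored scalar per layer, in both the training convention (batch-norm
affine terms, unfused reparameterizable branches) and the deployed
convention (batch norm folded, heads fused) — the deployed total is the
model-size figure quoted for these families. Graphs execute: `forward()`
runs a real multi-scale forward pass on an image array.

**Neural blocks as pure operators.** `pconv_forward()` (with the
`h·w·2c + k²c²` memory-access accounting in `pconv_memory_access()` — the
dominant-term ratio at the standard 1/4 channel fraction is exactly 1/4),
`fasternet_block()`, `c2f_faster()`, `hierarchical_contextualize()`,
`gated_aggregation()`, `focal_modulation()`, `elan_forward()`,
`repconv_forward()`/`repconv_fuse()` — all checked against direct-summation
oracles in the test suite.

**Evaluation stack.** Greedy confidence-ordered IoU matching
(`match_detections()`, with `TP + FN = |GT|` guaranteed),
`precision_recall()`, all-points interpolated `average_precision()`,
`mean_average_precision()`, and weather-stratified FP/FN-rate reporting
(`condition_report()`).

**Two-stage pipeline.** `screen_frames()` → `verify_frames()` →
`reconcile_counts()` (or `run_survey_pipeline()` in one call), with a
permissive screening threshold, a precision-oriented verification threshold
and within-frame duplicate merging.

**Synthetic survey scenes.** `generate_scene()` renders speckled elliptical
seals on low-contrast mudflat backgrounds with altitude-dependent target
sizes and four weather regimes (`apply_weather()`); `augment()` applies
geometry-consistent flips, affine warps, edge padding and canvas scaling;
`make_dataset()` writes PNG + Pascal-VOC XML + YOLO txt datasets with a
deterministic 9:1 train/validation split.

**Annotation I/O.** LabelImg-dialect VOC XML (`read_voc()`/`write_voc()`),
YOLO txt (`read_yolo_txt()`/`write_yolo_txt()`), and exact conversions
between the 1-based inclusive VOC edge, the normalized YOLO format and the
package's 0-based half-open boxes.

## Worked example

```r
library(sealscope)

count_parameters(build_ff_yolov10(nc = 1))
#> <param_report> ff_yolov10
#>   parameters (deploy): 1,888,742
#>   parameters (train) : 1,899,574
#>   analytic MACs      : 2.43 G

count_parameters(build_pp_yolov7(nc = 1))
#> <param_report> pp_yolov7
#>   parameters (deploy): 37,023,184
#>   parameters (train) : 37,747,760
#>   analytic MACs      : 33.37 G
```

The deployed onboard model stores 1,888,742 scalars — light enough for an
embedded accelerator — while the ground-station verifier stores 37,023,184;
that twenty-fold asymmetry is the point of the hierarchical design. A small
synthetic survey through the full pipeline, using the package's reference
contrast detector at both stages:

```r
frames <- list(); planted <- integer(12)
for (i in 1:12) {
  k <- (i * 3L) %% 5L   # 0-4 planted seals per frame
  sc <- generate_scene(scene_spec(canvas = 480, n_targets = k,
                                  contrast = 0.45, mottling = 0.03,
                                  seed = 100 + i))
  frames[[sprintf("frame_%02d", i)]] <- sc$image
  planted[i] <- k
}
det <- reference_detector()
run_survey_pipeline(frames, det, det, pipeline_config(tau1 = 0.25, tau2 = 0.5))
#> <survey_count> 24 seals in 10 verified frames (12 screened, 10 transmitted)
sum(planted)
#> [1] 24
```

Twelve frames were screened; the two all-background frames were never
transmitted, and the verified survey total (24) equals the planted total —
on high-contrast scenes the reference detector is exact, which is what lets
the test suite certify the matching, AP and counting arithmetic end to end.

See `vignettes/sealscope-methods.Rmd` for the models, the parameter-counting
conventions, the generator's assumptions and the package's design decisions.

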