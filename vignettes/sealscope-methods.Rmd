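---
title: "Models and design choices in sealscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in sealscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealscope)
```

## The monitoring problem

Spotted seals (*Phoca largha*) haul out on tidal mudflats where their
grey-black speckled dorsal pattern closely resembles the substrate. UAV
surveys photograph haul-outs from nadir at tens of metres of altitude, so an
adult seal occupies only a few hundred pixels of a frame, and the onboard
computer of a survey drone has a small fraction of the compute of a ground
workstation. `sealscope` implements a two-stage division of labour for this
setting:

1. an **onboard screener** — a lightweight single-class detector that runs on
   every captured frame and decides which frames contain candidate seals and
   are worth transmitting; and
2. a **ground-station verifier** — a much larger detector that re-analyses
   only the transmitted frames at high precision, after which per-frame
   counts are reconciled into a survey total.

The package provides the two detector families as declarative graphs with
exact parameter accounting, the neural building blocks behind them as pure
array operators, the single-class evaluation stack, the screening/verification
pipeline, and a synthetic scene generator that reproduces the statistical
character of the survey imagery so that every component is testable without
field data.

## The onboard family

The onboard detector derives from the n-scale NMS-free one-stage
architecture (consistent dual-assignment head, strides 8/16/32). Two
substitutions make it lighter:

**C2f-Faster.** Every split-transform-concat stage (C2f) keeps its entry and
exit pointwise convolutions and its dense-concat wiring, but its standard
bottlenecks are replaced by FasterNet residual units:

* a *partial convolution* (PConv): a dense $3\times3$ convolution applied to
  the first $c_p = c/4$ channels, with the remaining $3c/4$ channels passed
  through untouched. The full-form memory access cost of a convolution is
  $h w \cdot 2c + k^2 c^2$; the partial form costs
  $h w \cdot 2c_p + k^2 c_p^2$, and since the spatial term dominates, the
  ratio approaches $c_p / c = 1/4$ — one quarter of the standard cost
  (`pconv_memory_access()`);
* a pointwise expansion to $2c$ channels with channel normalization and GeLU
  — normalization and activation appear only after this intermediate
  pointwise layer, as in the reference FasterNet design;
* a bias-free pointwise projection back to $c$ channels and a residual
  addition.

The processed channels are a contiguous prefix, matching the
memory-locality rationale of the original design; the expansion factor is 2
and the partial fraction $1/4$ throughout.

**Focal modulation.** The spatial-pyramid-pooling block at the backbone tail
is replaced by an attention-free focal modulation operator. For input
$X \in \mathbb{R}^{H\times W\times C}$:

* hierarchical contextualization: $Z^{(0)} = f_z(X)$, then
  $Z^{(\ell)} = \mathrm{GeLU}(\mathrm{DWConv}_\ell(Z^{(\ell-1)}))$ for
  $\ell = 1\ldots L$, and a global level
  $Z^{(L+1)} = \mathrm{AvgPool}(Z^{(L)})$ broadcast back to the grid;
* gated aggregation: gates $G = f_g(X)$ with $L+1$ channels, one scalar per
  location per level, broadcast over channels:
  $Z_{\mathrm{out}} = \sum_{\ell=1}^{L+1} G^{\ell} \odot Z^{(\ell)}$;
* modulation: $y_i = q(x_i) \odot h(Z_{\mathrm{out},i})$, followed by an
  output projection.

The package configures $L = 2$ focal levels with depthwise kernels 3 and 5 at
the 256-channel tail position. This is the configuration whose parameter
budget matches the published size of the full onboard model; growing kernels
(3, 5) give the two levels strictly nested receptive fields, and the global
average pool supplies scene-level context. The interaction between query and
context is elementwise multiplication (modulation); the gate slice is a
scalar per location. The query, context, gate, modulator and output maps are
plain biased linear (1×1) projections with no normalization.

## The ground-station family

The verifier is the base-scale ELAN architecture: an ELAN backbone with
max-pooling downsampling transitions, an SPPCSPC tail, a PAFPN neck built
from ELAN-W aggregation blocks, and reparameterized convolution heads. Two
modifications target small, low-contrast seals:

**Module A — a fourth, stride-4 detection scale.** At 480×480 input the base
model predicts on 60×60, 30×30 and 15×15 grids; a seal of ~30 px then covers
at most four cells of the finest grid. Module A reduces the finest neck
level, upsamples it to 120×120, fuses it with the matching stride-4 backbone
feature by concatenation, aggregates with an ELAN-W block, and gives the new
level its own reparameterized head; a max-pooling transition returns the new
level to the bottom-up path so the deeper scales see its information. The
four heads carry implicit-knowledge terms: a learned additive per-channel
prior on each head input and a multiplicative prior on each output. The
mirror-the-existing-pattern design (reduce–upsample–route–aggregate–return)
keeps the module consistent with the rest of the neck; widths follow the
neighbouring stride-8 level at half scale.

**Module B — a partial convolution in the ELAN branch.** The designated CBS
convolution (convolution + normalization + activation) on the second branch
of the first backbone ELAN is replaced by a PConv whose processed width is
$1/4$ of the block's 256-channel aggregate width, i.e. all 64 channels of
that branch; being FasterNet-style it is bias-free, so the block sheds
exactly the folded bias while restricting computation to the processed
prefix. The swap is minimal by design: the first backbone stage sees the
highest-resolution features, where the speckled-seal/mudflat confusion
arises, and a single site keeps the verifier's capacity intact.

## Parameter accounting

`count_parameters()` reports two totals per graph:

* `total_train`: the training graph — convolutions are bias-free and
  followed by batch normalization whose two affine vectors are counted;
  reparameterizable convolutions carry their dense, pointwise and identity
  branches.
* `total` (deploy): the inference graph — batch normalization folded into a
  per-channel bias on the convolution, reparameterized convolutions fused to
  a single biased convolution, and, for the NMS-free family, only the
  one-to-one head retained (the one-to-many head exists only to train the
  dual-assignment scheme; `head = "full"` counts both). The 16-scalar
  integral-projection kernel of the box head is a fixed vector but is stored
  with the model and counted, following the family convention.

The deploy total is the figure quoted for deployed model sizes in this
model family and is what `scripts/acceptance.R` reports. Counts are exact
integer functions of the graph spec, independent of input data and
resolution; the analytic multiply-accumulate figure multiplies each layer's
weight count by its output positions at the graph's nominal resolution.

```{r counts}
count_parameters(build_ff_yolov10(nc = 1))
count_parameters(build_pp_yolov7(nc = 1))
```

## The two-stage pipeline

`screen_frames()` marks a frame positive when any stage-1 detection reaches
the screening threshold $\tau_1$; only positive frames are handed off.
`verify_frames()` re-detects the transmitted frames at the verification
threshold $\tau_2$; stage-2 boxes replace stage-1 boxes for counting
(stage-1 output is kept as provenance only). `reconcile_counts()` merges
near-duplicate boxes within a frame above a configurable IoU (default 0.9)
and sums per-frame counts.

Defaults are $\tau_1 = 0.25$ and $\tau_2 = 0.5$: screening is deliberately
permissive — a frame wrongly transmitted costs bandwidth, a frame wrongly
discarded loses animals irrecoverably — while verification is
precision-oriented because the survey total is read from stage 2. Counting
is per frame; re-identifying individuals across overlapping frames is out of
scope. Two properties are enforced by tests: frames are never verified
unless screened positive, and lowering $\tau_1$ never shrinks the
transmitted set.

## Evaluation stack

Boxes are 0-based half-open pixel rectangles package-wide. Matching is
greedy in descending confidence (ties broken by input order for
determinism): each detection takes the unmatched same-image ground-truth box
of highest IoU if that IoU reaches the threshold (default 0.5, the mAP@0.5
protocol). Precision is $TP/(TP+FP)$, recall $TP/(TP+FN)$, and
$TP + FN = |\mathrm{GT}|$ always. Average precision integrates the
all-points-interpolated precision envelope over recall (not the legacy
11-point rule), so AP depends only on the confidence ranking. The degenerate
no-detections case defines precision 1 (no claim made, none wrong), matching
the envelope's left end. Weather-stratified reporting defines the
false-positive rate as $FP/(TP+FP)$ and the false-negative rate as
$FN/(TP+FN)$ per condition; these quantities are not standardized in field
reports, so the package fixes these definitions explicitly.

## Synthetic scenes

`generate_scene()` renders: a mudflat background (muddy base hue, smoothed
low-frequency mottling, fine grain), and seals as rotated ellipses with
dorsal shading, per-pixel speckle and sparse light spots. The ground-truth
box of each seal is the minimum enclosing rectangle of its rendered body
pixels, and the noise-free label mask is returned for oracle checks. The
altitude proxy maps the two survey heights to major-axis ranges 28–44 px
(15 m) and 20–32 px (20 m) at 480 px canvas — assumed values chosen to keep
targets in the small-object band that motivates the stride-4 head, not
measured ones. Target/background luminance separation (`contrast`, default
0.25) is the difficulty knob emulating the speckle-on-mud failure mode.
Candidate footprints are expanded by one pixel during placement so an
overlap budget of zero guarantees separated bodies; infeasible packings
error after 200 retries per target.

Weather: fog blends toward a bright haze (contrast decreases strictly
monotonically in density), glare adds Gaussian bright patches, overcast
rescales gain and contrast, sunny is the identity. Augmentations (flips,
small-angle affine, edge padding, canvas scaling) transform boxes exactly
with the pixels — affine boxes are enclosing rectangles of the transformed
corners — then clip and drop degenerates.

Reproducibility: one master seed; per-image seeds are derived by counter so
any subset of a dataset regenerates identically. Validation splits take
round-half-up of the validation share (3036 frames at 9:1 → 2732/304).

What the generator does *not* emulate: perspective and lens distortion, wet
highlights and specular texture on animals, flocks of confounding objects
(birds, debris), and inter-frame correlation along a flight line. Passing
tests on synthetic scenes therefore certify the *software stack* — matching,
AP integration, the pipeline's counting discipline — not field-accuracy of
any detector.

## Numerical choices and degenerate inputs

* Convolutions are exact im2col/BLAS evaluations in double precision; block
  oracles agree with direct per-pixel summation to below $10^{-5}$.
* The C2f-Faster hidden width is `out_channels %/% 2`; odd remainders are
  absorbed by the output projection.
* `pconv_forward()` is pure (processed prefix convolved, remainder copied
  bit-identically); where a PConv replaces the convolution inside a CBS
  unit, the unit's activation is applied to the processed slice.
* Confidence ties in matching break by input order; duplicate-merge keeps
  the higher-confidence box.
* Zero-area boxes are dropped (with a warning) by the format converters;
  reversed or out-of-bounds VOC coordinates are rejected with the offending
  object identified.

## Scope and limitations

The package builds, counts, executes and evaluates detector graphs; it does
not train them — there is no automatic differentiation here, and weight
initialization exists to make forward passes and fusion identities testable.
Trainability of the graphs is therefore not demonstrated by this package.
The default test suite exercises full forward passes at 480×480 for the
onboard model and 96×96 for the ground-station family, and the end-to-end
pipeline check uses 200 synthetic frames at 480×480 — sizes chosen to keep
the default check fast while still covering every stride and scale
combination.
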