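---
title: "Attention-augmented ShuffleNet classifiers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-augmented ShuffleNet classifiers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`shufflecerv` implements a family of lightweight convolutional classifiers
for five-class cervical-lesion images — a ShuffleNet-style inverted residual
backbone, optionally fused with Squeeze-and-Excitation (SE) or
Selective-Kernel (SK) channel attention — together with the analytic
convolution-cost model, the data pipeline, the training recipe and the
evaluation suite.  This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data experiments do
and do not demonstrate.

## Why this architecture

Dense convolutions on a `(W, H, C_in)` feature map with `N × N` kernels and
`C_out` outputs cost `W·H·C_in·C_out·N²` multiplications.  Depthwise
separable convolution splits this into a per-channel spatial stage
(`W·H·C_in·N²`) and a 1×1 pointwise stage (`W·H·C_in·C_out`); the ratio of
the two costs is exactly `1/C_out + 1/N²`, independent of the spatial extent
and input width.  For a typical `3×3` layer with hundreds of output
channels this is roughly a nine-fold saving — the reason lightweight
backbones are built almost entirely from this factorization.  Note the
ratio exceeds 1 for `N = 1` with few outputs: the factorization is not
universally cheaper, and `reduction_ratio()` reports this honestly.

The package's cost model (`conv_mults()`, `dws_mults()`,
`model_complexity()`) counts multiplications only — no additions, no bias
multiplies — at each layer's output spatial dims under same padding.  Batch
norm contributes parameters but no counted multiplications; attention
modules contribute their linear-map and per-element rescaling
multiplications.  Serialized size assumes 4 bytes per parameter (single
precision, configurable); it is the parameter file size, not peak memory.
The whole model is validated in the test suite against an instrumented
naive convolution that performs the arithmetic and literally counts each
scalar multiply, over the exhaustive grid `W, H ≤ 4`, `C ≤ 8`,
`N ∈ {1, 3, 5}`.

## The units

A **stride-1 unit** on `C` channels (C even throughout the backbone):

1. channel split into halves `X1`, `X2` (floor rule on odd counts, which the
   default schedules never produce);
2. `X2` → 1×1 conv → BN → ReLU → 3×3 depthwise conv → BN → *attention* →
   1×1 conv → BN → ReLU;
3. concatenate `(X1, X2')`, channel shuffle with `G = 2`.

The shuffle is the pure permutation that sends input channel `g·n + i` to
output position `i·G + g` (`n = C/G`) — reshape to `(G, n)`, transpose,
flatten.  It is a bijection, and shuffling with `C/G` groups inverts it.
Because `X1` is untouched, the unit carries an exact identity path without
any addition; stacking units and shuffling mixes deep and shallow features.

A **stride-2 unit** has no split: branch A is depthwise(stride 2) → BN → 1×1
→ BN → ReLU on the full input; branch B is 1×1 → BN → ReLU →
depthwise(stride 2) → BN → *attention* → 1×1 → BN → ReLU; each branch emits
`channels_out/2`, the concat is shuffled with `G = 2`.  Descriptions of
this unit family typically cover only the stride-1 split unit; the stride-2
form follows the family's standard design, which is the only way to build a
staged backbone from these parts.

**Attention placement.** SE or SK is applied to the depthwise-convolution
output (after its BN) inside each unit — the point where channel
re-weighting acts on spatially aggregated features; SK is placed identically
to SE so the two are comparable.

## Attention modules

**SE.** Squeeze: `z_c = mean(U_c)` (global average pool).  Excite:
`s = sigmoid(W2 · relu(W1 · z + b1) + b2)` with bottleneck width
`⌈C/r⌉`.  Output: `s_c · U_c`.  Gates lie strictly in (0, 1), so SE can
only attenuate — per-channel output magnitude never exceeds the input — and
pinning the gates to 1 recovers the identity.  The excitation is often
described only loosely — an activation plus a linear mapping — so the
two-layer ReLU/sigmoid bottleneck used here is the canonical completion and
is exposed as configuration.  The reduction ratio `r` likewise has no
single canonical value; the default is 16, the value this module family
conventionally uses, and it is an `attention_config()` field, not a
constant.

**SK.** Two depthwise-separable 3×3 branches at dilation 1 and dilation 2
(padding 1 and 2, so both preserve spatial dims and differ only in
receptive field: 3×3 vs effectively 5×5).  The branches are summed, pooled
to a channel descriptor, passed through a shared bottleneck (`⌈C/r⌉`,
ReLU), and two per-branch linear heads produce channel scores.  Describing
this pooling as "like the SE attention" leaves ambiguous how the two branch
scores become weights: independent sigmoids (the literal SE reading) or a
softmax across branches (the convention of selective-kernel designs).  The
default is the softmax,
chosen for its convexity property (`w1 + w2 = 1` per channel, so the output
is a convex combination of the branches); `sk_norm = "sigmoid"` switches to
the literal reading.  The branch convolutions carry no BN of their own —
they sit between BN layers of the host unit.

## Backbone

`model_config()` defaults to the canonical 1.0× schedule of this unit
family: 3×3 stride-2 stem to 24 channels (BN, ReLU), 3×3/2 max pool, stages
of 4/8/4 units at 116/232/464 channels (each stage one stride-2 unit then
stride-1 units), a final 1×1 convolution to 1024 channels, global average
pooling, and a linear head with 5 logits.  The unit fixes the topology but
not the stage widths, so the schedule is fully overridable;
`model_config_small()` (stages 2/2/2 at 48/96/192, final 512) is the
package's reduced schedule for CPU-scale experiments — same topology, about
a quarter of the compute.  At the default width the three variants count
1,258,729 / 1,305,501 / 2,040,245 parameters (baseline / SE / SK); the SE
excess is exactly one excitation bottleneck per unit,
`Σ (2·C_b·⌈C_b/16⌉ + ⌈C_b/16⌉ + C_b)` over branch widths `C_b`.

Activation is ReLU throughout and every convolution is followed by batch
norm (momentum 0.1, eps 1e-5, biased variance); the unit's recipe calls
for batch normalization plus an activation without pinning down which, and
ReLU is the family default.  Weights are Kaiming-style
normal draws scaled by fan-in, BN starts at scale 1 / shift 0, and all
initialization flows from the R RNG, so a seed fixes the build bit-for-bit.

## Implementation note

No deep-learning framework is used: forward and backward passes for every
layer (convolutions via im2col and direct depthwise kernels in C++;
batch norm, attention, shuffle, pooling and the heads in vectorized R) are
implemented in the package, as is the Nesterov SGD update
(`v ← μv + g + λp`, `p ← p − η(g + μv)`).  Every layer's analytic gradient
is finite-difference-checked in development; the suite retains
oracle-vs-implementation checks for the convolutions and the composed
units.

## Data pipeline

Datasets use the image-folder layout `root/<label>/*.png|jpg` with labels
0 normal, 1 LSIL, 2 HSIL, 3 cervical cancer, 4 cervical neoplasm.  The
split protocol is stratified 90/10 at image level: per-class train counts
are rounded half-up, then balanced to within one record of the global 90%
target, and the split is a seeded deterministic partition.  Image-level
splitting of multi-image patients leaks patient identity between subsets;
`stratified_split(grouped = TRUE)` keeps `group_id` groups intact for a
leakage-free (approximately stratified) alternative.  The default follows
the stated image-level protocol.

Training augmentation applies, in order: shorter-side resize (default
target 256, so arbitrary inputs cover the crop; skipped when images already
do), random 224×224 crop, random horizontal and vertical flips (p = 0.5),
and per-channel standardization `(x − mean)/sd`.  Standardization
statistics are computed from the training split by default (the protocol
names no fixed constants); fixed constants can be passed instead.
Augmentation is applied on the fly each epoch rather than by offline
dataset inflation — the clinical per-class counts sum to the stated total,
implying counts are tallied pre-augmentation.  Evaluation uses
the deterministic resize → center crop → standardize counterpart.

## The synthetic generator

`generate_synthetic_dataset()` renders five visually distinct classes from
per-class generative parameters: a base hue (defaults spread over the color
circle, so mean image hue is monotone in class index), a count of bright
elliptical blobs, a sinusoidal texture frequency, and i.i.d. Gaussian pixel
noise.  Default per-class counts mirror the clinical class-imbalance
profile 2352:780:2532:408:924 scaled by a configurable divisor (floor).  At
`noise_sd = 0` the classes are separable from mean color alone — a
1-nearest-neighbor classifier on mean RGB is perfect, which the tests
assert — and they grow confusable as noise rises.

The generator emulates the *structure* of the classification problem (class
count, imbalance, RGB images, reproducibility), not its clinical content:
real colposcopy images differ by subtle morphology under shared anatomy and
illumination, not by global hue.  Training runs that succeed on the
generator therefore validate the optimization and evaluation machinery —
that the architecture can fit and generalize on a seeded image task — and
say nothing about clinical accuracy.  Clinical-scale results for this
architecture family require a hospital colposcopy dataset and GPU-scale
100-epoch training, both out of scope here.

## Training recipe and problem sizes

`train_control()` defaults to the stated recipe: SGD-Nesterov, initial
learning rate 0.05, momentum 0.9, weight decay 1e-4 (applied to all
parameters, the framework-default convention), batch size 32, 100 epochs.
The recipe fixes only the initial learning rate; the default schedule
here is linear decay to zero (`lr_at()`), with cosine and constant
available.  The loss is cross-entropy on logits.  Divergence (non-finite
loss) aborts with an error naming the epoch.  The best-validation-epoch
weights are retained as the fitted model.

The package's own experiments (test suite and acceptance script) run at
desk scale: 50 images per class at 64×64 and zero noise, 90/10 split,
10 epochs at batch 32 on the reduced `model_config_small()` schedule —
under which every variant reaches 100% (occasionally 96%) validation
accuracy — plus a single-batch memorization check (8 images, reached within
a handful of steps).  The default 16-unit full-width schedule is built for
thousands of images over 100 epochs; in the 10-epoch small-data regime its
optimization is still settling (best validation accuracy ~84% in
development runs), which is why the reduced schedule is the documented
configuration at this problem size.

## Evaluation

`evaluate()` produces a K×K confusion matrix (rows true, columns
predicted); `per_class_counts()` marginalizes TP/FP/FN/TN per class.
Metrics are on the percent scale: accuracy `100·trace/total`; per-class
precision `100·TP/(TP+FP)`, recall `100·TP/(TP+FN)`,
F1 `100·2PR/(P+R)`.  Since the per-class definitions are binary and a
single summary per metric is conventional, both averages are reported:
macro (unweighted class mean — unlike the micro average it can exceed
overall accuracy, e.g. for a weak model that is precise on rarely predicted
classes) and micro (pooled counts, which collapses to accuracy for
single-label data).  Division by zero (empty predicted or true class) yields 0 with a
warning, or the class can be excluded from macro means.  Row-normalizing
the confusion matrix puts per-class recall on the diagonal, the standard
reading of normalized confusion plots.

AUC is one-vs-rest per class via the midrank (Mann–Whitney) statistic —
ties counted half, equal to trapezoidal ROC integration — with macro and
micro (pooled) averages; since the convention behind a reported scalar AUC
(single class, macro or micro) is often left unstated, all are available.
The
implementation is checked against exhaustive pair counting and against an
established ROC package.  `repeated_runs()` implements the mean ± sample-sd
(n−1) protocol over independent seeds; one run reports sd as absent.

## Numerical choices and degenerate inputs

- Same padding everywhere: `pad = dilation·(N−1)/2`, output dims
  `ceil(dim/stride)`; required for the split unit's concat to type-check.
- Channel split fraction fixed at ½/½ with floor on odd counts; `C = 2`,
  `G = 2` shuffle is well defined by the index map (identity).
- Softmax ties in `predict()` break to the lowest class index.
- BN uses batch statistics in training and running statistics (momentum
  0.1) at evaluation; variance is clamped at 0.
- Probabilities from logits use max-shifted softmax; cross-entropy clamps
  probabilities at 1e-12.
- Checkpoints are RDS files with the model configuration embedded as JSON,
  so a checkpoint is self-describing.

## Limitations

- Grouped 1×1 convolutions (the older variant of this family) are not
  implemented; the described unit does not use them.
- No pretrained weights or transfer learning; no DICOM or
  colposcope-metadata handling; no latency or memory-access-cost modeling.
- CPU-only: practical problem sizes are thousands of small images, not the
  224×224/100-epoch clinical regime.
- The synthetic benchmark certifies machinery, not clinical performance
  (see above).
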