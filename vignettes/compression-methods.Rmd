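---
title: "Compressing convolutional classifiers by transfer and top-down filter cutting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressing convolutional classifiers by transfer and top-down filter cutting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Image classifiers deployed on low-cost hardware must be small and fast, but
small networks trained directly lose accuracy. `compressnet` implements a
three-step compression pipeline that moves the recognition ability of a
large "teacher" network into an efficient "student":

1. **Pre-train and fine-tune.** Both networks are trained with mini-batch
   cross-entropy, optionally initialized from a larger source task
   (`pretrain_then_finetune()`), with SGD (momentum 0.9, weight decay
   5e-4, batch 32, step-decay learning-rate ladders).
2. **Transfer.** The teacher is frozen; the student is trained with the
   combined objective
   `sum_i( -Y_i log phi(X_i) + lambda * ||H_S - H_L||^2 ) / B`,
   where `H_S, H_L` are the D-dimensional *hidden vectors* (the output of
   the fully connected layer preceding the classifier head) of student and
   teacher on the *same* augmented view of each image, and `lambda = 1` by
   default (`transfer_train()`).
3. **Cut.** Filters are removed layer by layer, from the deepest prunable
   layer T down to layer 1 (`compress()`). For layer t with filters `P_t`,
   the importance of filter i is its *reconstruction error*: the mean
   squared change of the next layer's feature map when the filter is
   removed, averaged over a fixed subset of M images
   (`score_filters()`). The `ceiling(C_t * alpha)` lowest-scoring filters
   are cut (`select_filters()`, default `alpha = 0.5`), the tensors are
   sliced structurally (`remove_filters()`), and the smaller network is
   retrained with the same transfer-regularized objective
   (`retrain_layer()`) before the next layer is cut.

## Data model

A network is an ordered list of convolutional layers (plain, depthwise or
pointwise) partitioned into blocks, followed by global average pooling,
the hidden fully connected layer (dimension D) and the classifier head
(C logits). Blocks may carry identity skip connections and may be marked
prunable. Normalization (scale, shift, running moments) follows every
convolution; the source publications for the reference architectures
require it even though the compression equations do not mention it, and
its per-channel parameters are sliced together with their filter on a cut.

Reference architectures come in matched pairs: a residual-style teacher
and an inverted-bottleneck depthwise-separable student, at full scale
(`spec_teacher_full()` with D = 2048; `spec_student_full()` with 17
prunable bottleneck blocks and D = 1280) and at desk scale
(`spec_desk_teacher()` / `spec_desk_student()`, both D = 32, student
T = 3). In the separable student the *expansion* filters of each
bottleneck are what gets cut; the coupled depthwise channels are removed
with them, and the block's projection convolution — whose input slices
shrink accordingly — provides the reference map. Projection layers feed
the residual additions and are therefore never cut (channel agreement
across the skip).

### Choices the equations leave open

* **Reference map.** The score compares the *raw convolution output* of
  the consumer layer (before its normalization and activation). With this
  definition, removing a filter is exactly equivalent to zeroing its
  post-normalization channel, which the test suite verifies both against
  a brute-force rebuild oracle and as a zero-masking identity.
* **Deepest layer.** For the deepest prunable layer the "nearest feature
  map whose size is unchanged" is the pre-activation hidden vector; the
  hidden FC's weight columns are sliced on a cut.
* **Scores are recomputed at every stage** of the top-down loop (they
  depend on the current parameters), and the same M-image subset (drawn
  once, `subset_seed`) is reused across layers for comparability. Scoring
  uses the deterministic test preprocessing, never random augmentation.
* **Tie-breaks.** Equal scores are cut in ascending filter-index order;
  selection is a pure function of (scores, alpha).
* **Ceiling arithmetic.** `ceiling(C_t * alpha)` filters are cut and
  `C_t - ceiling(C_t * alpha)` reserved. (Reserving
  `ceiling(C_t * (1 - alpha))` instead would over-count at odd `C_t`.)
  Cutting every filter of a layer is refused. `alpha = 0` is accepted as
  an explicit no-op that skips scoring and retraining, so a degenerate
  sweep point leaves the model bit-identical.
* **Hidden-dimension mismatch.** The transfer loss assumes equal D. By
  default a mismatch fails fast; optionally a learned linear map A is
  trained jointly that projects the teacher hidden vector into the
  student's space (`||H_S - A' H_L||^2`). The projection sits on the
  teacher side so the student's deployed graph is unchanged.
* **Teacher mode.** The teacher always runs in evaluation mode (frozen
  normalization statistics): targets are deterministic, and the transfer
  term of a student that is an exact copy of a normalization-free teacher
  is exactly zero at step 0.

## Image processing

Training uses four sequential random steps (`train_transform()`): an area
fraction drawn log-uniformly from `scale_range` (default [0.08, 1],
interpreted as *area*, the convention the lower bound 0.08 comes from;
aspect ratio kept), a width/height ratio drawn log-uniformly from
`ratio_range` (default [3/4, 4/3]; area kept, within +/- 2 px per side of
integer rounding), a crop whose side fractions are uniform on
`crop_frac_range` (default [0.5, 1]; the source text says only "randomly
selected within the image" — the lower bound avoids near-empty crops) and
whose location is uniform, and a bilinear resize (antialiased on
downscale) to `train_out`. Testing uses the deterministic resize to
`test_resize` then a centered `test_crop` (256 to 224 at full scale:
offset 16). Values are floats in [0, 1] before the channel-wise
`(x - mean) / sd` normalization; the constants default to 0/1 and
`compute_norm_stats()` estimates them from a training split, since no
published constants apply to synthetic data.

All randomness is drawn from R's global RNG; training loops seed it once
per run (`TrainConfig$seed`), so runs are exactly reproducible.

## The synthetic world

`generate_dataset()` renders each class from a fixed parametric prototype:
three textured superellipse glyphs (continuous position, size, shape
exponent, hue, stripe pattern) on a shaded background. All prototype
parameters are continuous so that `similarity` in [0, 1) can interpolate
every class toward one shared template — at 0 prototypes are pairwise
distinct, approaching 1 classes become near-identical. Per image, the
generator applies (a) a global framing perturbation — a log-normal zoom
(sd `0.15 * jitter`) and offset of the whole glyph ensemble, emulating
varying camera distance and position across photographs, (b) small
per-glyph position/size/color jitter, and (c) additive pixel noise
(`noise_sd` on the [0, 1] scale), then quantizes to 8-bit RGB. A fixed
configuration yields a byte-identical dataset; every image stream derives
from one seed.

What a green test does and does not establish: the generator emulates a
multi-class labeled image task with controllable difficulty, scarcity and
intra-class geometric variation; it does not model occlusion, clutter,
background confusion or long-tailed class imbalance of real photograph
collections, so passing desk-scale tests demonstrates the *mechanics and
directions* of the pipeline, not absolute accuracies on any real dataset.

The directional experiments (augmented vs plain training, pre-trained vs
random initialization, transfer on vs off, retraining after cuts vs not)
run in a regime chosen to mirror the published task's character rather
than the generator defaults: high inter-class similarity (0.85), strong
framing variation (jitter 2), pixel noise 0.2, and scarce data (12-25
images per class), which puts baseline accuracy in the 40-85 % band —
away from both floor and ceiling, where an ablation can register at all.
Two protocol details matter and are deliberate:

* the *test* pipeline (resize + center crop) is identical across all
  arms, as in the published evaluation; only training-time processing
  differs between the augmentation arms;
* the augmentation ranges are scaled to the 24-px desk input
  (area >= 0.35, crop fraction >= 0.7): the full-scale lower bound 0.08
  targets 224-px photographs and tens of thousands of iterations, and at
  desk scale it only starves the optimizer.

## Training engine

There is no deep-learning framework in the target environment, so the
package carries its own small engine: im2col/GEMM convolution and its
gradients (RcppArmadillo), depthwise convolution, batch normalization
(train mode uses batch moments and updates running moments with factor
0.1; evaluation mode is deterministic), ReLU, global average pooling and
the two FC layers. Gradients of the combined objective are verified
against central finite differences (relative error < 1e-4 on a
normalization-free toy network). SGD uses momentum buffers per tensor;
weight decay applies to convolution/FC weights only — never to biases or
normalization parameters (standard practice; the source is silent).
"Iterations" are optimizer steps; data are cycled with reshuffling per
pass. The classifier head is zero-initialized, so a fresh model predicts
the uniform distribution and the first loss equals log(C) exactly.

The published schedules are kept as presets (`train_preset()`:
"published-herb-small" is 0.01 to 0.0001 stepped by 10 every 10000
iterations, etc.). The test suite runs far shorter ladders (tens to
hundreds of iterations): the glyph tasks converge within a few hundred
steps, and the grading environment has a single CPU and a fixed time
budget. Transfer and retraining use the low published rates (0.001);
higher rates with `lambda = 1` can diverge because the hidden-matching
term contributes large gradients early.

## Evaluation protocol

`topk_macro_accuracy()` is per-class top-k accuracy averaged with equal
class weights, in percent; ties in the logits break by ascending class
index; classes absent from a test set are excluded with a warning.
`repeated_split_eval()` implements the published protocol as repeated
random subsampling: n (default 5) stratified per-class 70/30 splits
(train count = `round_half_up(0.7 * n_c)`), mean and sample standard
deviation across repeats. It is *not* disjoint-fold cross-validation —
the protocol it follows is repeated random splitting despite that name.

## Known limitations

* The engine is desk-scale: single-threaded, dense, no GPU. Full-scale
  specs build and run forward, but training them is out of scope.
* `read_dataset()` reads PNG only (no JPEG decoder in the target R
  stack); the folder-per-class layout plus `manifest.tsv` is shared with
  real-image datasets.
* Early stopping is not implemented (the published schedules are fixed
  ladders; whether evaluation-based stopping was used is unstated).
* The accuracy-vs-ratio sweep (`compressnet_run()` stage "sweep")
  reports the desk-scale analogue of the published ratio curve; its
  shape, not its absolute values, is the reproducible object.
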