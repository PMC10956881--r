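---
title: "Methods: dynamic sparse attention for skin lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic sparse attention for skin lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dermoscopic images show pigmented skin lesions whose boundaries fade
gradually into the surrounding skin, whose size and shape vary enormously
between patients, and which are frequently crossed by hairs and other
clutter. Binary segmentation of the lesion area is the first step of most
automated melanoma-screening pipelines, and the combination of blurred
boundaries and heterogeneous lesion types is what makes it hard for plain
cascaded-convolution architectures: repeated local filtering neither
suppresses background clutter nor models relationships that span the whole
image, let alone regularities shared *across* images.

`hdsnet` implements a U-shaped encoder–decoder that attacks both
shortcomings with a hybrid encoder: a group-normalized residual CNN
extracts local features, and a **dynamic sparse attention** (DSA) block at
the bottleneck couples them to global, sample-independent context through
two learnable external memory units.

## The model

### Encoder

The convolutional part of the encoder follows the classic 4-stage residual
bottleneck design (block counts 3, 4, 6, 3; a 7×7/2 stem followed by 3×3/2
max-pooling). All normalization is **group normalization**: statistics are
computed per sample over channel groups (at most 32, capped at the largest
divisor of the channel count), never over the batch, so a batch of one
behaves exactly like a batch of eight and train/eval normalization is
identical. The last stage keeps stride 16 rather than descending to 1/32,
so the exposed feature pyramid sits at 1/2, 1/4, 1/8 and 1/16 of the input
resolution; the first three levels feed skip connections and the 1/16 map
feeds the attention bottleneck.

The channel widths are the canonical (64, 256, 512, 1024, 2048) multiplied
by a global factor that was fixed **once**, before any training, so that
the complete network reproduces the published design budget of ≈24.36 M
parameters and ≈8.67 G multiply–accumulates at 224×224. The frozen values
are a multiplier of 0.78125 (stem 50; stages 200/400/800/1600) together
with decoder widths 256/128/64/32, giving 24.50 M parameters and 8.64 G
MACs (`count_parameters()`, `count_flops()`). Within the stated budgets
this is the only calibration the architecture receives; a strictly halving
four-stage layout without the pooling stage was rejected because no width
assignment can satisfy the parameter and FLOP budgets simultaneously (its
high-resolution stages are too expensive per parameter).

### Dynamic sparse attention

Let `X` be the bottleneck map of shape (B, C, H, W) and `S = H·W`. The
block computes

    Q   = reshape(conv1x1(X))            # (B, C, S)
    M   = Q ⊙ K                          # element-wise scores
    A   = softmax_S(M)                   # normalized over the token axis
    α   = A ⊙ B_p                        # Bernoulli 0/1 mask, keep-prob p
    O   = α ⊙ V
    out = conv1x1(reshape⁻¹(O))

`K` and `V` are **external memory units**: learnable (S × C) arrays that do
not depend on the current sample, so they can store correlations between
lesions seen across the whole training set. Every product above is
element-wise — there is no query–key matrix multiplication — which biases
the block toward local, position-aligned comparisons while the shared
memories provide the global/context pathway. The random mask `B_p`
(independent Bernoulli draws with keep-probability `p`, the *sparsity
ratio*) randomly discards a fraction `1 − p` of the normalized attention
mass each forward pass, suppressing redundant background responses and
acting as a stochastic regularizer.

Design points that the block's description leaves open, and the choices
made here:

* **Order of softmax and masking.** The normalization is applied first and
  the mask second (softmax → mask → ⊙V). This makes `p` a literal
  keep-ratio of attention mass and matches the procedural description of
  the computation; the alternative reading (softmax applied outermost to
  the whole product) is rejected because masking after normalization is
  what gives the sparsity ratio its stated meaning.
* **Softmax axis.** Over the token axis S, i.e. over spatial positions,
  separately per channel and sample — the standard attention reading; it
  is also what makes uniform scores produce a uniform attention map.
* **The linear maps.** Realized as the two 1×1 convolutions plus one
  learnable element-wise scaling per memory unit (`sK ⊙ K`, `sV ⊙ V`); no
  dense layers, keeping every operation element-wise and the parameter
  count inside the budget.
* **Mask granularity.** One independent draw per (token, channel, sample)
  — fully element-wise, resampled at every training forward pass.
* **Evaluation mode.** The mask is replaced by its expectation (every
  entry `= p`), dropout-style, so reported test metrics are deterministic;
  sampling at inference would make them random variables. At `p = 1` train
  and eval modes coincide exactly.
* **No residual path inside the block.** The block output is exactly the
  projected attention output; consequently `p = 0` zeroes the block — a
  degenerate but valid configuration.

The default sparsity ratio is 0.9, the value found best in the original
ablation across three benchmarks; `hds_sweep()` re-runs that ablation
protocol (shared initialization and data, one train/evaluate cycle per
ratio) at any scale.

### Decoder and output

Three transpose-convolution (2×2, stride 2) up-stages double the
resolution and concatenate the matching skip feature (1/8, 1/4, 1/2), each
followed by a 3×3 convolution with group norm and ReLU; a final transpose
convolution restores full resolution and a 1×1 projection (no intermediate
nonlinearity) emits one logit per pixel. Probabilities are `sigmoid`
(logits), binarized at 0.5 by default.

## Loss and metrics

Training minimizes `L = L_Dice + L_BCE` on the sigmoid probabilities: the
soft Dice term `1 − (2Σpt + s)/(Σp + Σt + s)` (smoothing `s = 1` for
differentiability at empty masks) counters the foreground/background class
imbalance, and the mean binary cross-entropy term (probabilities clamped
to `[1e-7, 1 − 1e-7]`) stabilizes the gradients.

Evaluation uses pixel confusion counts: IoU = TP/(TP+FP+FN),
Sen = TP/(TP+FN), Spe = TN/(TN+FP), Dice = 2TP/(FP+2TP+FN), with
`Dice = 2·IoU/(1+IoU)` as an algebraic invariant the tests enforce.
Metrics are computed per image and averaged over images (the challenge
convention), not pooled over pixels. When prediction and truth are both
empty a metric with zero denominator is reported as 1 (nothing to find,
nothing found); when only one is empty, Dice and IoU are 0.

## Optimization

Plain SGD with the published settings: initial learning rate 0.01,
momentum 0.9, weight decay 1e-4, batch size 24, 300 epochs, constant
learning rate (`lr_schedule` exists as a hook but ships as the identity).
Weight decay is applied uniformly to all trainable tensors. Because the
test metrics are reported from a single run, checkpoint selection uses the
best held-out Dice. All randomness — initialization, shuffling, attention
masks — derives from explicit seeds, so a CPU run is bit-reproducible.

The entire network, including backpropagation, is implemented in this
package: im2col-based convolution kernels (compiled, BLAS-backed),
transpose convolutions, max-pooling, group normalization and the attention
block each carry hand-derived backward passes. The test suite validates
the complete gradient against central finite differences end to end, and
the attention forward against an independent scalar-loop oracle.

## Synthetic data

The generator emulates the specific difficulties named above rather than
photorealism:

* **irregular shapes** — lesions are star-convex polygons: radii at 12
  equally spaced control points are perturbed multiplicatively
  (relative s.d. 0.3) and interpolated with a periodic spline;
* **blurred boundaries** — the lesion is alpha-blended with a Gaussian
  blur of σ = 1.5 px applied to its support; the stored mask is always the
  exact, un-blurred support;
* **size variation** — target area fractions are drawn uniformly from
  (0.05, 0.4) of the image, enforced after rasterization;
* **hair-like clutter** — up to five dark quadratic Bézier strokes
  (radius 0.6–1.4 px) are drawn *after* blending, so they occlude the
  lesion as real hairs do;
* skin and lesion colors are jittered per sample around realistic RGB
  means, over a low-frequency texture field.

What the generator does **not** emulate: dermoscopic rulers and gel
bubbles, multi-focal lesions, the intensity statistics of any real
archive, or inter-device color variation. Tests passing on synthetic data
therefore demonstrate that the implementation is correct and trainable —
not that the architecture reaches any particular accuracy on clinical
images, which requires the external challenge datasets and GPU-scale
training and is explicitly outside this package's scope.

Datasets are written in the standard challenge layout
(`ISIC_<id>.jpg` + `ISIC_<id>_segmentation.png`) so the reader
(`index_dataset()`, `split_dataset()`, `load_batch()`) treats real and
synthetic data identically. The random 8:2 split takes
`floor(0.8·N)` training records — published per-dataset counts do not all
satisfy an exact 8:2 of their totals, so a fixed, documented rounding rule
is used instead of reproducing those counts — and is a pure function of
the sorted id set and the seed, independent of directory order. Masks
stored as 8-bit PNGs are binarized at >127 (they are nominally 0/255).
Images are bilinearly resized to the network input (default 224×224, the
published setting); masks use nearest-neighbor resizing and re-binarization.
No augmentation is applied (none is specified for the original training
recipe); a hook exists in the configuration but ships empty.

## Problem sizes used by the tests

The packaged experiments are sized for a single CPU: gradient checks run
on a 16×16-input model with one block per stage; behavioral tests use a
width-scale-0.125 model at 64×64; the overfit-sanity experiment trains a
width-scale-0.25 model on eight 64×64 synthetic images for 200 SGD steps
(learning rate 0.01, momentum 0.9 — the published settings) and requires
train-set Dice ≥ 0.95; the design-budget checks build the full default
model. `scripts/acceptance.R` re-runs the same protocol end to end from a
seed and writes the measured quantities as JSON.

## Known limitations

* Training at the published scale (224×224, batch 24, 300 epochs) is
  possible but slow in this implementation; it targets desk-scale
  experiments, not GPU benchmarks.
* The memory units are sized for one bottleneck resolution: a model is
  built for a fixed input size, and feeding another size raises a
  configuration error rather than interpolating the memories.
* Exact stage/width assignments of the original encoder and decoder are
  not published; the frozen configuration here is the one that meets the
  published parameter/FLOP budgets, and other assignments meeting them
  would be equally admissible.
* Sensitivity/specificity averaging (per image, as here, versus pixel
  pooling) is a convention choice; pooled values differ on heterogeneous
  test sets.
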