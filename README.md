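# hdsnet

Binary segmentation of skin lesions in dermoscopic images with a U-shaped
encoder–decoder whose bottleneck is a **dynamic sparse attention** (DSA)
block: element-wise external attention against two learnable,
sample-independent memory units, filtered by a random Bernoulli 0/1 mask
whose keep-probability — the *sparsity ratio* `p` — is a tunable
hyperparameter. The package is aimed at researchers who want to study this
attention mechanism (its sparsity ratio, its memory units, its training
behavior) on a single CPU, with fully reproducible runs and no external
data: a synthetic dermoscopy generator provides ISIC-layout datasets with
exact masks.

Everything is implemented in the package itself — forward passes,
hand-derived backpropagation (im2col convolutions in compiled code, group
normalization, transpose-convolution decoding, the attention block) and
SGD — because no deep-learning framework is assumed.

## The model

The encoder is a group-normalized residual network (bottleneck blocks
3/4/6/3, widths 200/400/800/1600 = the classic 256…2048 layout × 0.78125)
producing features at 1/2, 1/4, 1/8 (skip connections) and 1/16
(bottleneck). At the bottleneck, with `Q = reshape(conv1x1(X))` of shape
(B, C, S), `S = H·W`:

    M   = Q ⊙ K                 element-wise scores against memory K
    A   = softmax_S(M)          normalized over spatial tokens
    α   = A ⊙ B_p               Bernoulli mask, P(keep) = p   (default 0.9)
    out = conv1x1(reshape⁻¹(α ⊙ V))

`K`, `V` are learnable (S × C) memory units shared across samples; all
products are element-wise. At evaluation the mask is replaced by its
expectation, so inference is deterministic. A transpose-convolution
decoder with skip concatenations restores full resolution; training
minimizes `L = L_Dice + L_BCE` with SGD (lr 0.01, momentum 0.9, weight
decay 1e-4, batch 24, 300 epochs by default). Evaluation reports
per-image Dice, IoU, sensitivity and specificity
(`Dice = 2·IoU/(1+IoU)`).

The default configuration reproduces the design budget of the published
architecture: **24.50 M parameters** and **8.64 G MACs** at 224×224
(`hds_summary()`).

## Worked example

Generate a synthetic dataset, split it 8:2, train a quarter-width model at
64×64 for 200 SGD steps, and evaluate on the held-out images:

```r
library(hdsnet)

dir <- tempfile("lesions")
generate_dataset(10, lesion_params(image_size = c(64, 64)), dir, seed = 2)
idx   <- split_dataset(index_dataset(dir), ratio = 0.8, seed = 1)
train <- load_batch(idx[idx$split == "train", ], c(64, 64))
test  <- load_batch(idx[idx$split == "test", ],  c(64, 64))

cfg   <- hds_config(input_size = c(64, 64), width_scale = 0.25)
model <- build_model(cfg, seed = 42)
fit   <- hds_train(model, train,
                   train_config(batch_size = 8, epochs = 200, seed = 1),
                   max_steps = 200)

round(head(fit$history$loss, 3), 3)   # 1.392 1.382 1.367
round(tail(fit$history$loss, 1), 3)   # 0.083

ev <- hds_evaluate(fit$model, test$images, test$masks)
round(unlist(ev$summary), 3)
#>  dice   iou   sen   spe
#> 0.960 0.923 0.940 0.994
```

The loss falls from 1.39 to 0.08 over 200 steps and the two held-out
images are segmented with Dice 0.96 — the model has learned to separate
lesion from skin despite blurred boundaries and hair clutter. The
sparsity-ratio ablation protocol is one call
(`hds_sweep(seq(0.1, 1, 0.1), cfg, tcfg, train, test)`), and
`hds_predict()` writes binary PNG masks at the original image resolution.

A profile of the full-scale reference model:

```r
hds_summary(hds_config())
#> input size      : 224 x 224
#> encoder widths  : stem 50 | stages 200/400/800/1600
#> decoder widths  : 256/128/64/32
#> sparsity ratio  : 0.90
#> parameters      : 24.50 M (24502819)
#> forward MACs    : 8.64 G
```

A command-line interface wrapping the same functions is installed at
`inst/cli/hdsnet` (subcommands `synth`, `train`, `eval`, `sweep`,
`predict`, `summary`).

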