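# capseg

Lightweight semantic segmentation of 2-D medical images in R: a pyramid
scene parsing network on a MobileNetV2-style dilated backbone, with
coordinate-attention blocks wrapped around backbone feature extraction and
a mixed Dice + Focal training loss aimed at class imbalance and small
lesions (tumours in CT slices, polyps in colonoscopy frames, lesions in
dermoscopy photographs).

The package is self-contained: there is no deep-learning framework
dependency. Convolutions, batch normalisation, bilinear resampling,
adaptive pooling and their gradients are implemented in the package
(RcppArmadillo GEMM cores plus a compiled single-precision training
executor), and a synthetic lesion-image generator stands in for clinical
data so the entire pipeline — data, training, evaluation — runs on one CPU
in minutes with no download.

## The model

The network has four parts:

1. **Backbone** — MobileNetV2 inverted-residual extractor (canonical
   schedule, width 1.0), truncated before the 1280-channel head. At output
   stride 8 the stride-2 blocks of the 64- and 160-channel stages run with
   stride 1 and dilation 2 and 4, so the deepest map keeps 1/8 resolution.
2. **Coordinate attention (CA)** — before and after the inverted-residual
   stack. For input `x` with C channels, two strip pools
   `z^h_c(h) = mean_i x_c(h, i)` and `z^w_c(w) = mean_j x_c(j, w)` are
   concatenated, squeezed by a shared 1x1 convolution to
   `max(8, C/r)` channels (r = 16), normalised, activated, split, restored
   to C channels by two independent 1x1 convolutions and gated through
   sigmoids; the map is reweighted as
   `y_c(i, j) = x_c(i, j) * g^h_c(i) * g^w_c(j)`.
3. **Pyramid pooling** — the deep map is average-pooled to 1x1, 2x2, 3x3
   and 6x6 grids, each branch compressed to 80 channels and upsampled, all
   concatenated with the deep map (640 channels) and fused by a 3x3
   convolution.
4. **Classifier** — 1x1 convolution to K classes, bilinear upsampling to
   the input size, per-pixel softmax.

Training minimises the mixed loss

    L = lambda * DiceLoss + (1 - lambda) * FocalLoss
    DiceLoss  = 1 - (2 * sum(G_i P_i) + eps) / (sum(G_i) + sum(P_i) + eps)
    FocalLoss = mean( -alpha * (1 - p_t)^gamma * log(p_t) )

with `lambda = 0.6`, `alpha = 0.25`, `gamma = 2` by default. Evaluation
reports mIoU, mPA, precision, recall and global pixel accuracy from pooled
per-class confusion counts.

## Worked example

```r
library(capseg)

# parameter accounting of the default network
net <- make_network(network_config(), seed = 1)
parameter_breakdown(net)
#>   backbone        ca1        ca2        ppm       head classifier      total
#>    1811712        856      19900     103040     460960        162    2396630
count_parameters(net) / 1e6
#> [1] 2.39663

# synthetic lesion dataset: 200 images, 97 x 97, high-contrast lesions
idx <- generate_dataset(synth_config(preset = "easy", seed = 11), "synth_easy")
table(idx$split)
#> test train   val
#>   20   160    20

# 15 epochs of seeded SGD on one CPU (a few minutes)
cfg <- train_config(epochs = 15, seed = 1, lr = 0.15,
                    net = network_config(input_side = 97))
run <- train_model(cfg, idx, verbose = TRUE)
evaluate_model(run, idx, "test")$report
```

The breakdown above is the exact learnable-scalar count per module; the
2.40 M total is the budget that makes the network light enough for CPU
inference. On the easy synthetic preset the trained model reaches a
validation foreground IoU above 0.80 within 15 epochs; a plain intensity
threshold reaches about 0.93 on the same data, which is the sanity floor
any trained model must approach.

A thin CLI over the same functions lives at `inst/cli/capseg.R`
(`synth`, `train`, `eval`, `sweep`, `params`, `predict` subcommands).

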