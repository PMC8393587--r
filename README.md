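# nbac

Boundary-aware semantic segmentation for 2D images and 3D volumes in R,
built around the **narrow-band active contour (NB-AC) loss**.

## The problem

Medical segmentation data are dominated by two pathologies. *Class
imbalance*: the background routinely covers 90%+ of the pixels, so
pixel-wise losses (cross entropy, Dice, Focal) let the majority class
dominate the gradient. *Weak boundaries*: adjacent tissues with overlapping
intensity distributions (e.g. gray vs white matter in infant brain MRI)
leave almost no local evidence of the edge. Both problems concentrate
exactly where pixel-wise losses pay the least attention — near the boundary.

## The model

`nbac` trains a two-branch encoder–decoder (2D/3D U-Net or FCN):

* the **region branch** outputs class probabilities `p` with categorical
  cross entropy `L1`;
* the **contour branch** pushes the final decoder features through a
  *transitional gate* — a fixed 3×3 gradient stencil χ then a `B × B`
  grayscale dilation ζ — giving a contour map `F_LC` and narrow-band map
  `F_LN = ζ(χ(F_H))`.

The NB-AC loss on the second branch restricts a Chan–Vese style region
energy to the narrow band of the ground-truth boundary, with band `ζ(χ(y))`
split into inner/outer sub-bands `B_in`, `B_out` and descriptors `b_in`,
`b_out` (the sub-band means of `p`):

```
L2 = μ · mean|F_LC|  +  λ_in · mean_{B_in}(p − b_in)²  +  λ_out · mean_{B_out}(p − b_out)²
L  = λ1·L1 + λ2·L2,   λ1 = λ2 = 0.5
```

Pixels outside the band contribute nothing — the loss is an implicit
under-sampler that neutralises class imbalance while focusing capacity on
the weak boundary. Baselines (CE, Dice, Focal, offset-curve OsC) and the
classic Chan–Vese energy are included, every loss and operator is verified
against brute-force per-pixel oracles, and a seeded phantom generator
reproduces both pathologies so the whole package runs download-free on one
CPU. Networks are trained by the package's own reverse-mode differentiation
in base R (BLAS matrix products) — no external deep-learning framework.

## Worked example

```r
library(nbac)

# weak-boundary phantoms: 3 classes whose means sit 0.1 apart, noise sd 0.05
cfg <- phantom_config(dims = c(64, 64), K = 3, contrast_gap = 0.1,
                      noise_sigma = 0.05, seed = 7)
ph <- make_phantom(cfg)
round(ph$realized_proportions, 3)
#> [1] 0.70 0.15 0.15

data <- lapply(1:24, function(i) {
  icfg <- cfg; icfg$seed <- cfg$seed + i * 7919L
  make_phantom(icfg)
})

fit <- nbac_fit(data, nbac_config(
  backbone = backbone_config("unet2d", num_classes = 3, depth = 2,
                             base_width = 8),
  loss = "nbac", steps = 60, batch_size = 8, val_every = 20, seed = 1))
fit
#> <nbac_model> unet2d + nbac loss | 60 steps | best val macro-Dice 0.8708
#>   K = 3, depth = 2, base_width = 8 | seed 1 | config 0c8f73d3

evaluate_segmentation(predict(fit, data[[2]]$image), data[[2]]$mask, K = 3)
#> <nbac_metrics> K = 3
#>  class   dice    iou precision recall n_pred n_truth
#>      0 0.9869 0.9741    0.9912 0.9826   2842    2867
#>      1 0.7558 0.6075    0.8879 0.6580    455     614
#>      2 0.8685 0.7675    0.7685 0.9984    799     615
#> macro (foreground): dice 0.8122 | iou 0.6875 | pre 0.8282 | rec 0.8282
```

The per-class rows are Dice, IoU, precision and recall (Dice is the F-score
and equals `2·IoU/(1+IoU)`); the macro line averages the foreground classes,
the convention used for published structure scores. Longer runs on the full
study set (64 phantoms, 150 steps) reach macro-Dice around 0.95. Loss
comparisons in the style of a benchmark table come from `nbac_compare()`,
and a script launcher (`synth` / `train` / `eval` / `compare` / `audit`,
YAML-configured) is installed at
`system.file("cli", "nbac.R", package = "nbac")`.

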