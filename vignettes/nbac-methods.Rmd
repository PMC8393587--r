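---
title: "Narrow-band active contour losses: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Narrow-band active contour losses: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbac)
```

## The problem

Pixel-wise segmentation losses (cross entropy, Dice, Focal) treat every pixel
as an independent classification case. On medical images this runs into two
pathologies. First, class imbalance: background often exceeds 90% of the
pixels, so the majority class dominates the gradient. Second, weak
boundaries: adjacent tissues whose intensity distributions overlap (infant
gray vs white matter being the canonical example) leave almost no local
evidence of where the edge is, and a pixel-wise loss has no mechanism to
concentrate effort there.

The remedy implemented here is an attention mechanism derived from
region-based active contours. The classic Chan–Vese functional scores a
candidate contour by the intensity homogeneity of the regions inside and
outside it, plus length and area regularisers; `chan_vese_energy()`
implements it as an evaluation-only reference. Its weakness is the global
homogeneity assumption. The narrow-band variant keeps the homogeneity
criterion but restricts it to a fixed-width band around the boundary — the
pixels that actually decide where the contour sits. Restricting the energy to
the band is simultaneously an implicit under-sampler: pixels far from any
boundary (overwhelmingly background) contribute nothing, which addresses the
imbalance pathology without reweighting.

## The two-branch model

`nbac_fit()` trains an encoder–decoder network with two heads:

* **First branch (region):** a standard U-Net or FCN produces per-class
  logits; its loss `L1` is the categorical cross entropy (`region_loss()`).
* **Second branch (contour):** the final decoder feature map `F_H` passes
  through a residual refinement block and then a *transitional gate*: an
  edge-extraction operator χ (a fixed 3×3 gradient-magnitude stencil) gives
  the contour map `F_LC`, and a grayscale dilation ζ with a `B × B` window
  gives the narrow-band map `F_LN = ζ(χ(F_H))`.

The second-branch loss is the narrow-band active contour loss

$$ L_2 \;=\; \mu\,\overline{|F_{LC}|}
   \;+\; \lambda_{in}\,\overline{(p - b_{in})^2}\big|_{B_{in}}
   \;+\; \lambda_{out}\,\overline{(p - b_{out})^2}\big|_{B_{out}}, $$

where the band of the ground-truth mask `y` is `ζ(χ(y))`, its inner/outer
sub-bands split it by `y`, `p` is the predicted class probability, and
`b_in`, `b_out` are the mean responses over the sub-bands (the *descriptors*,
`band_descriptors()`). The first term is a discrete contour-length penalty on
the predicted edge map. The total loss is
`λ1 L1 + λ2 L2` with `λ1 = λ2 = 0.5` (`nbac_total_loss()`), and both branches
are trained end to end: gradients from `L2` reach the shared encoder through
the gate.

### Band-energy modes

The separate-band form of the loss (integrals over `B_in` and `B_out`) and
its whole-domain rewrite (integrals of `p·F_LN` over all of Ω with
band-weighted descriptors) are not algebraically equivalent, so the package
exposes both, plus an intermediate, as `band_mode` in `nbac_weights()`:

* `two_sided` (default) — energies over the inner/outer sub-bands of the
  ground-truth band with sub-band mean descriptors. This is the form that
  matches the stated homogeneity criterion of the inner and outer bands and
  is what training uses unless told otherwise.
* `band_vs_complement` — grayscale-band-weighted energy against its
  complement, descriptors as band-weighted means.
* `literal_eq14` — the whole-domain form exactly as printed.

Each mode is verified against an independent per-pixel loop oracle in the
test suite. Which form the original experiments used is not determinable from
the text; the default was chosen on the stated criterion, not on benchmark
results.

### Operator choices

* **χ is fixed, not learned.** The source architecture describes χ as a 3×3
  convolutional layer without stating whether it is trainable. The package
  default is the fixed smoothed central-difference (Sobel) stencil,
  normalised so a unit ramp has gradient magnitude exactly 1: fixed kernels
  make every operator test deterministic and keep the contour map
  interpretable. A learnable variant (kernels initialised to the stencil) is
  available via `band_spec(trainable_edge = TRUE)`.
* **Band width `B`.** Never stated numerically in the source; defaults are
  `B = 5` in 2D and `B = 3` in 3D (pixels/voxels, isotropic spacing 1),
  chosen as the smallest widths that give the band interior structure on
  desk-scale images. Configurable in `band_spec()`.
* **Boundary handling** is replicate padding for both χ and ζ (the source is
  silent); the signed distance (`signed_distance()`) is the exact Euclidean
  transform measured pixel-centre to pixel-centre (no half-pixel boundary
  offset), positive inside.
* **Sub-band splitting** uses the binarised indicator `band > 0` on the
  exact test path, while the raw grayscale band serves as a soft weight on
  the differentiable path.

### Numerical choices

* Probabilities are clipped to `[1e-7, 1 - 1e-7]` before logarithms; the
  Dice loss uses a smoothing constant `1e-6` in numerator and denominator.
  Both are unstated numerical guards.
* All band energies are normalised by their domain's pixel count. The
  continuous formulation integrates unnormalised; normalisation keeps the
  μ-, inner- and outer-terms on comparable scales across image sizes and is
  switch-free by design (documented here once).
* Descriptors are treated as per-step constants by the gradient
  (`detach_descriptors = TRUE`), the standard treatment of region means in
  Chan–Vese-style optimisation. For mean descriptors over their own domain
  the detached and full gradients coincide identically (the residuals sum to
  zero); in `literal_eq14` mode they differ and both are implemented and
  gradient-checked.
* Degenerate inputs: a constant mask has no band — band terms are skipped
  with a warning rather than silently evaluating 0/0; an all-foreground or
  all-background mask is an error for `signed_distance()`; an empty
  descriptor domain is an error in `band_descriptors()`.
* Losses λ, μ in the band loss default to 1 (unstated in the source); the
  branch weights 0.5/0.5 are as stated. The OsC baseline's ε defaults to 1.
* Adam defaults mirror the reference setup: learning rate `1e-2` with weight
  decay `1e-4` in 2D, `2e-4` in 3D. An optional global gradient-norm clip
  and a NaN guard (abort with a diagnostic batch dump) are off by default
  and flagged in the log when active.

### Network details

U-Net levels follow the two-convolutions-per-level recipe (3×3 kernels, batch
normalisation and ReLU in 2D; 3×3×3, instance normalisation and leaky ReLU in
3D), max-pooling down, bilinear upsampling plus skip concatenation up. The
FCN variant is a 7-stage FCN-32-style stack with poolings after stages 1–5;
"conv1, conv3, conv7" are mapped to the outputs of stages 1, 3 and 7, each
projected by a 1×1 convolution and fused at input resolution by bilinear
interpolation — the exact stage wiring is underdetermined in the source and
this mapping is the package's judgement call. The second branch uses one
residual block (two convolutions plus identity skip) at full resolution
before the gate; the source figure does not specify the count or placement,
and one block is the minimal faithful realisation (configurable via
`n_res_blocks`). The second branch consumes only the final decoder feature
map, not multi-scale taps. Multi-class band losses are computed per
foreground class against that class's one-hot band and averaged; in
`literal_eq14` mode the channelwise narrow-band map is averaged over channels
to a single field before entering the energy.

All layers, and the reverse-mode differentiation that trains them, are
implemented in base R with BLAS-backed matrix products (shift-and-multiply
convolution); no deep-learning framework is involved. This bounds the
practical problem size — see *Scale* below.

## The synthetic phantom generator

`make_phantom()` emulates the two target pathologies without any external
data:

* **Weak boundaries:** per-class mean intensities sit `contrast_gap` apart
  in `[0, 1]` (default adjacent gap 0.1, i.e. twice the default noise sd of
  0.05 — near-touching distributions), with optional per-class spread,
  global Gaussian noise, and a low-frequency multiplicative bias field.
  `class_separation()` verifies the knob is monotone: smaller gaps give
  smaller Bhattacharyya separation between adjacent-class histograms.
* **Class imbalance:** target class proportions are hit by quantile
  thresholding of a smooth random field (`blobs`, `nested_rings`), which
  realises them essentially exactly; `vessels` draws 1–3 px spline tubes and
  retries until within 20% relative of the target.

The generator is seeded and bit-reproducible. What it does *not* emulate:
MRI physics (partial volume, Rician noise, acquisition artefacts), anatomy
(plausible shapes, inter-subject variability), anisotropic voxels, or
multi-modal channels with realistic correlations. Passing tests on phantoms
therefore demonstrate the correctness and trainability of the losses and
architecture, and the qualitative boundary/imbalance behaviour — not
clinical-grade segmentation accuracy on real data.

## Scale and the built-in experiments

The test suite and the acceptance script run the full study on one CPU: 64
training plus 16 held-out 64×64 three-class weak-boundary phantoms
(contrast gap 0.1, noise 0.05), a depth-2, width-8 2D U-Net, batch 8, 150
optimisation steps, three seeds. Under these conditions the NB-AC-trained
network reaches held-out foreground macro-Dice around 0.95, and the loss
comparison harness (`nbac_compare()`) reproduces a benchmark-table-shaped
CSV over {CE, Dice, Focal, NB-AC} × 3 seeds. These sizes were chosen so the
whole pipeline — including every brute-force oracle — runs in minutes; the
model, not the scale, is the subject. The validation split inside
`nbac_fit()` is deterministic (items whose derived seed is divisible by 5,
roughly 20%, are held out for checkpoint selection), since the source states
no split rule.

## Known limitations

* Pure-R training is practical up to roughly 128×128 2D batches or small 3D
  patches; it is not a GPU training stack.
* The OsC baseline treats the signed distance field, its band and the
  descriptors of the thresholded prediction as per-step constants; its
  length term is reported but contributes no gradient.
* 2D PNG datasets are 8-bit quantised on disk; NIfTI volumes are stored at
  full precision.
* Batch-norm running statistics are taken from the training stream
  (momentum 0.1); very short runs therefore validate with statistics close
  to the last batches.
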