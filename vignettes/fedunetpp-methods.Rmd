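---
title: "FED-UNet++: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FED-UNet++: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fedunetpp)
```

## The problem

Hippocampus segmentation in T1-weighted MRI slices is an extreme
small-structure problem: the target typically covers on the order of 0.2% of
the pixels of a 256×256 slice, it is slender and curved, and its boundary is
low-contrast and blurred. Plain overall pixel accuracy is therefore nearly
meaningless (an all-background predictor scores ≈99.8%), and the metrics that
matter are overlap ratios (IoU, Dice) and boundary distances (HD95).

`fedunetpp` implements FED-UNet++, a nested encoder–decoder network designed
for this regime, together with everything needed to train and evaluate it on
CPU without external data: a compound BCE+Dice loss, the standard metric set,
a deterministic crescent-phantom generator, and profiling utilities. Because
no deep-learning framework is available to R in this environment, the package
carries its own small reverse-mode automatic-differentiation engine
(`R/autograd.R`, `R/ops-*.R`): convolutions are evaluated as im2col + BLAS
matrix products, and every operation's backward pass is verified against
finite differences in the test suite.

## Architecture

The backbone is the U-Net++ grid of nodes $X^{i,j}$ ($0 \le i+j \le 4$).
Node $X^{i,j}$ receives the channel concatenation of all $X^{i,k}$, $k<j$,
plus a 2× bilinear upsampling of $X^{i+1,j-1}$; the encoder spine
($j=0$) downsamples with 2×2 max pooling. Default widths are
$(32, 64, 128, 256, 512)$; a single 1×1 head on $X^{0,4}$ emits logits. At
these widths the plain U-Net++ baseline has exactly 9,163,329 trainable
parameters (9.16 M).

Three module families modify this backbone:

**FRBlock (residual feature reconstruction).** Replaces the two-convolution
unit everywhere:

$$F_1 = \mathrm{ELU}(\mathrm{BN}(\mathrm{Conv}_{3\times3}(X))), \quad
  F_2 = \mathrm{ELU}(\mathrm{Conv}_{3\times3}(\mathrm{ELU}(\mathrm{Conv}_{1\times1}(F_1))))$$
$$F_{\text{fused}} = \mathrm{ELU}(\mathrm{BN}(\mathrm{Conv}_{1\times1}([F_1, F_2]))), \quad
  Y = \mathrm{ELU}(F_{\text{fused}} + \mathrm{Shortcut}(X))$$

The shortcut is the identity when $C_{in}=C_{out}$, a 1×1 convolution
otherwise. The internal width is $C_{mid} = C_{out}/2$ and the serial
$1{\times}1/3{\times}3$ path carries no batch norm; this is the unique simple
configuration under which the 64→64 block has 33,120 parameters (0.0331 M),
i.e. about half the 74,112 (0.0741 M) of the VGG-style block it replaces, and
under which the full FRBlock network totals 4.68 M against the 9.16 M
baseline. All convolutions carry biases.

**EAP (efficient attention pyramid)**, inserted after the bottleneck node
$X^{4,0}$ (512 channels, preserved). Five parallel branches — a 1×1
convolution, three 3×3 atrous convolutions at dilations 6/12/18, and a global
average-pooling branch (1×1 conv, broadcast back) — each followed by BN+ELU,
are concatenated to $5C$ channels and compressed back to $C$. The directional
gate then averages the compressed map over width (per-row descriptors) and
over height (per-column descriptors), concatenates the two descriptor
sequences along the spatial axis, passes them through a shared 1×1 bottleneck
(reduction 16), splits, maps each back to $C$ channels and applies a sigmoid.
The attention map is the rank-1 outer product of the row gate and the column
gate — literally an $H{\times}1$ by $1{\times}W$ matrix multiplication — and
the output is $F_r \odot A + F_r$, so the gate can only modulate between
$1{\times}$ and $2{\times}$ the compressed features. The module adds ≈8.97 M
parameters at $C=512$, dominated by the dilated branches.

**DFCN (dynamic frequency context network)**, applied after the blocks of the
deep decoder nodes $X^{0,2}, X^{0,3}, X^{0,4}$ (width 32, full resolution). A
1×1 convolution doubles the channels, the result is split into two branches,
each passes a depthwise 3×3 convolution, and a GELU-gated product
$\mathrm{GELU}(X_1)\odot X_2$ forms the local map. That one local map is then
filtered in parallel at three patch scales $P \in \{4, 8, 16\}$: the map is
tiled into non-overlapping $P{\times}P$ patches (reflect-padded to the next
multiple of $P$ when needed, cropped afterwards), each patch is transformed
by a 2D real FFT, multiplied bin-wise by a learnable real amplitude weight
$W_f^{(s)}$ of shape $(C, P, P/2{+}1)$, and inverse-transformed. The three
filtered maps are concatenated ($3C$) and projected back to $C$ by a 1×1
convolution.

## Loss and metrics

Training minimizes

$$L = w_{\mathrm{BCE}}\,\mathrm{BCE}(\sigma(z), t) +
      w_{\mathrm{Dice}}\,(1 - \mathrm{softDice}),\qquad
  \mathrm{softDice} = \frac{2\sum_i p_i t_i + \varepsilon}
                           {\sum_i p_i + \sum_i t_i + \varepsilon},\ \varepsilon = 1,$$

with default weights 0.5/0.5; BCE is computed in the numerically stable
logits form and the Dice term per image, averaged over the batch. The
smoothing $\varepsilon$ exists only in the loss; evaluation metrics use raw
confusion counts: IoU, Dice, recall, precision, accuracy, with the
conventions that empty-vs-empty masks count as perfect agreement and that
precision of an empty prediction against a nonempty reference is 0
(pessimistic, never favourable to the model). HD95 is the larger of the two
directed 95th-percentile nearest-neighbour Euclidean distances between
boundary pixel sets, where a boundary pixel is a foreground pixel with at
least one background 4-neighbour (image borders count as background) and the
percentile interpolates linearly between order statistics (`quantile`
type 7). An HD95 involving an empty mask is reported as `NA` with a warning,
never silently 0. Predictions are thresholded at probability ≥ 0.5 before
metrics are computed.

## Training protocol

Defaults (see `train_config()`): Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with
L2 weight decay 1e-4, initial learning rate 1e-3 annealed per epoch by

$$\mathrm{lr}(e) = \mathrm{lr}_{\min} + \tfrac12(\mathrm{lr}_{0} -
  \mathrm{lr}_{\min})\,(1 + \cos(\pi e/E)),$$

to 1e-5, 300 epochs, batch size 16, inputs at 256×256. Flip and 90°-rotation
augmentation are available and off by default. Batch normalization uses batch
statistics with momentum 0.1 and ε = 1e-5 during training and running
statistics at evaluation. Training aborts loudly on a non-finite loss rather
than propagating NaNs. Every `cmd_train()` run writes a per-epoch log, a
config snapshot and its MD5 digest as the run hash, and a single-file
checkpoint holding the building configuration, all weights and the
normalization statistics.

## Numerical and initialization choices

* **Weight initialization** is He-normal for convolutions; frequency weights
  start at 1 (the spectral path is then exactly the identity, so the network
  begins training as a purely spatial model).
* **Zero-initialized head.** The GELU-gated product in DFCN multiplies
  feature magnitudes, and its output re-enters later decoder stages through
  the FRBlock shortcut convolutions, which bypass batch norm; at He scale the
  activation magnitude therefore compounds across the three DFCN nodes
  (measured activation std at the last decoder node: thousands). Two
  initialization choices keep the starting point sane: the 1×1 logit head is
  zero-initialized (the untrained network outputs probability 0.5 everywhere
  and the initial loss sits at its natural ≈0.8 level), and the DFCN
  projection convolution is initialized at gain 0.2 so the module is roughly
  scale-preserving at the start of training. Both are initialization-only
  devices; nothing constrains the weights afterwards.
* **FFT conventions.** Unnormalized forward transform, $1/P^2$ inverse (the
  common "backward" convention); for the small patch sizes used the 2D DFT of
  a tile stack is evaluated as two dense complex matrix products, vectorized
  over all tiles, channels and batch. Amplitude weights are stored on the
  half-spectrum grid of a real FFT; within the self-conjugate DC and Nyquist
  columns, conjugate bin pairs are tied to one weight, because a real
  amplitude filter must weight a bin and its conjugate equally — otherwise
  the filtered spectrum loses Hermitian symmetry and energy is silently
  discarded when the real part is taken. The tied duplicate storage entries
  receive zero gradient (the same redundancy exists in rfft storage).
* **Resampling.** Decoder upsampling is separable bilinear interpolation with
  half-pixel centers; max-pooling ties route the gradient to the first
  maximal position in a fixed scan order.
* **Padding.** Convolutions use zero "same" padding; the patch tiler uses
  symmetric reflection (edge not repeated) to avoid spectral edge artifacts,
  and crops after the inverse transform.
* **Thresholds.** `predict_mask()` uses `>=`, so an exactly-0.5 probability
  map is foreground at the default threshold.

## The phantom generator

`make_phantom()` draws a crescent — a bent annulus sector with mean radius
$0.15\,S/\text{curvature}$, angular half-width 70°, and thickness solved from
the requested foreground fraction — at a seeded random position and
orientation. The mask is the crisp crescent; the image is a smooth background
texture (blurred white noise around a base level of 60) plus
`contrast` × (Gaussian-blurred crescent) plus additive Gaussian noise,
clipped to [0, 255]. Defaults (256 px, foreground fraction 0.002, contrast
60, blur 1.5, noise 10) emulate the regime of hippocampus MRI slices: extreme
class imbalance, a slender curved target, low contrast and indistinct
boundaries. `make_dataset()` writes PNG pairs with a manifest and assigns
each phantom identity to exactly one split, mirroring subject-exclusive
partitioning; `add_gaussian_noise()` implements the robustness perturbation
(σ = 15 on the 0–255 scale in the reference protocol).

What the phantoms do *not* emulate: MRI physics (bias fields, Rician noise,
partial-volume effects), anatomical context (neighbouring structures with
confusable intensities), or inter-subject anatomical variability. Passing
phantom tests therefore demonstrates that the architecture, gradients, loss,
metrics and training loop are correct and that the assembled network can
learn small curved low-contrast targets — not that the published clinical
accuracy transfers to any particular dataset.

## Problem sizes used by the tests

The test suite and the acceptance script keep everything CPU-sized: the
trainability check uses widths (8, 16, 32, 64, 128) — the published
architecture at one quarter width — on eight 64×64 phantoms for 30 epochs at
batch size 2 (Adam 1e-3, cosine to 1e-5), which reaches a mean training Dice
above 0.95 in a few minutes on one core. At 64×64 the study-scale foreground
fraction of 0.002 would leave a target of roughly 8 pixels, below the
resolution of any segmentation network, so the smoke phantoms use a
proportionally larger fraction of 0.03 with contrast 180, blur 0.8 and noise
8. Noise-direction evaluation (σ = 15 versus clean) uses the four held-out
test phantoms of the same dataset. Parameter-count checks build the
full-width architecture (exact counts are resolution-independent); forward
shape contracts are exercised at full width on 64×64 inputs and at reduced
width on larger inputs.

## Known limitations

* CPU-only and R-native: throughput is adequate for the reduced problem
  sizes above, not for 300-epoch training at 256×256 and batch 16.
* 2D slices only; no volumetric (3D) variant.
* The published parameter count for the frequency module at 64/64 channels
  (0.0269 M) is not reproducible under any disclosed weight layout (our
  faithful layout gives 0.0345 M), and the corresponding full-network row
  (5.90 M, below the 9.16 M baseline) is arithmetically inconsistent with
  adding a module; neither number is used as a check. The block-level and
  baseline counts (0.0741 M, 0.0331 M, 9.16 M, 4.68 M) are reproduced
  exactly.
* Comparison baselines (SwinUNet, PSPNet, DeepLabv3+) are out of scope, as is
  GPU profiling (inference time, VRAM).
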