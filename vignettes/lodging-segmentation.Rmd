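---
title: "Mapping crop lodging with compact attention-augmented segmentation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping crop lodging with compact attention-augmented segmentation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgeseg)
```

## The problem

Rice lodging — stems bent flat by wind, rain or over-fertilisation — cuts
yield and has to be located quickly over large paddies. Aerial RGB
orthomosaics make that possible, but lodged and upright canopy share very
similar colours: what separates them is mostly *texture* (flattened,
differently oriented straw versus upright planting rows) and *context*.
Per-pixel semantic segmentation with compact convolutional networks is the
standard tool, and two training-time techniques make small, deployable
models competitive:

1. a **global attention block** that re-weights convolutional feature maps
   using pairwise affinities between all spatial positions, and
2. **channel-wise knowledge distillation**, which trains a small student
   to match the softened spatial distributions of a large trained teacher.

This package implements both, together with the surrounding machinery
(compact encoder–decoder models with atrous spatial pyramid pooling,
receptive-field and cost profilers, the orthomosaic tiling protocol, and
mIoU evaluation) and a synthetic lodged-field generator so that every
component can be exercised end-to-end on a desktop CPU.

## The global attention block

Given a feature map $X \in \mathbb{R}^{H\times W\times C}$, the block
flattens it row-major to $(HW) \times C$ and applies:

$$Z = X_f W_1 + b_1 \in \mathbb{R}^{HW \times C'}$$

a first linear layer shrinking channels to an embedding width $C'$
(default 64) so the quadratic affinity below stays affordable at any $C$.
A second linear layer maps $Z$ to width $3C'$ and is chunked contiguously
into query/key/value matrices $M_1, M_2, M_3 \in \mathbb{R}^{HW\times C'}$.
The **global affinity**

$$M_I = M_1 M_2^{\top} \in \mathbb{R}^{HW \times HW}$$

holds the dot-product similarity between every pair of spatial positions,
giving each output position a global receptive field. The aggregated map
$M_R = M_I M_3$ is recalibrated by a two-layer MLP
(linear–ReLU–linear, no channel reduction), reshaped back to
$H \times W \times C'$, squeezed over channels by average pooling to a
single-channel refined map $A_R$, and applied residually:

$$\tilde X = (A_R + 1) \otimes X,$$

with $A_R$ broadcast along channels. A zero-initialised block is therefore
an exact identity, which makes insertion into a pretrained network safe.

Design points that the block's description leaves open, and the choices
made here:

* **No softmax or normalisation on $M_I$.** The affinity is used raw. An
  optional $1/\sqrt{C'}$ scaling (`affinity_scaling`) exists purely for
  numerical headroom on large grids and is off by default.
* **MLP nonlinearity.** A rectifier between the two MLP layers, none
  after the second — the standard recipe for recalibration MLPs. The MLP
  operates on the flattened $(HW)\times C'$ matrix before reshaping
  (mathematically equivalent to operating after).
* **No activation on $A_R$.** The residual form $(A_R + 1)\otimes X$ is
  applied literally, so attention values may amplify or damp features
  without a sigmoid squashing.
* **Biases everywhere.** All four linear layers carry biases, and
  `gattn_param_count()` counts them.
* **Flattening convention.** Row-major over the image (h-major, then w);
  `gattn_recalibrate()` inverts the same convention. The `trace` returned
  by `gattn_forward()` exposes every intermediate
  ($Z, M_1, M_2, M_3, M_I, M_R, A, A_R$) for inspection and testing.
* **Initialisation.** Fan-based uniform draws
  ($\pm 1/\sqrt{\text{fan-in}}$), seedable; degenerate $1\times 1$ inputs
  are legal ($M_I$ is $1\times 1$). An alternative `identity_start`
  scheme zeroes the second MLP layer so the freshly inserted block is an
  exact identity and its signal grows from nothing — useful when the
  surrounding network trains from scratch.

## Segmentation models

`build_segmodel()` assembles a compact encoder–decoder: a stride-2 stem,
stages that each open with a stride-2 transition convolution and continue
with stride-1 blocks (residual, plain, or bottleneck style per family),
then an ASPP decoder — three parallel atrous convolutions at distinct
rates plus a pointwise branch, concatenated, projected and classified —
with bilinear upsampling of the logits to label resolution before any
loss. Inputs in $[0,1]$ are centred to $[-1,1]$ at the stem.

Attention blocks are inserted per (stage, block): the branch reads the
block input and re-weights the block's main-path output before the
residual addition. The default insertion is the final block of the last
two stages, where the spatial grid — and hence the $(HW)^2$ affinity — is
smallest. Attention parameters live under `.attn.` checkpoint keys, so a
backbone-only checkpoint loads cleanly and leaves the attention freshly
initialised (`load_pretrained()` reports exactly what was loaded and
skipped).

The model zoo is deliberately width-reduced (tens of thousands of
parameters, not millions): these are the same architectural ingredients
as the full-size networks, at a scale where a complete train/evaluate
cycle takes seconds on one CPU core.

Receptive fields follow
$RF = 1 + \sum_i (k_i - 1)\, r_i \prod_{j<i} s_j$: two stacked 3×3
convolutions see 5×5; dilating the second to rate 2 extends that to 7×7
with no extra parameters — the motivation for atrous rates in the ASPP
head. The profiler cross-checks this analytic count against brute-force
impulse probing in the test suite. Cost estimates are MAC-based (2 FLOPs
per multiply-accumulate), with the attention affinity and aggregation
contributing $2(HW)^2 C'$ each.

## Channel-wise distillation

The student is trained on

$$L_{\text{Total}} = L_{\text{CE}} + \alpha\, L_{\text{KD}},$$

where $L_{\text{CE}}$ is the usual per-pixel cross-entropy over the $K$
classes, and the distillation term compares **per-channel spatial
distributions**: each output channel $c$ is turned into a probability
vector over its $HW$ positions by a temperature softmax

$$\theta(Y_c)_i = \frac{\exp(Y_{c,i}/T)}{\sum_{j=1}^{HW} \exp(Y_{c,j}/T)},$$

and

$$L_{\text{KD}} = \frac{T^2}{C}\sum_{c=1}^{C}\sum_{i=1}^{HW}
  \theta(Y^T_{c,i})\,\log\frac{\theta(Y^T_{c,i})}{\theta(Y^S_{c,i})}.$$

The two losses normalise over **different axes on purpose**: CE over
classes per pixel, KD over positions per channel. $T>1$ softens the
spatial distributions so that the teacher's relative emphasis across the
image — not just its hard argmax — carries gradient signal; the $T^2$
factor compensates the $1/T^2$ gradient shrinkage the temperature
introduces (the test suite checks the gradient magnitude stays within a
constant factor across $T \in \{1,2,4,8\}$). Defaults are $T = 4$ and
$\alpha = 3$. Distillation acts on the final upsampled logits; the
teacher is run in inference mode, detached from gradient flow, and is
never modified. Probabilities are floored at $10^{-12}$ inside the
logarithm. Whether to mask the background channel out of the KD sum is an
open question in the underlying method; this implementation distils all
channels, background included, which is the simpler contract and keeps
the loss exactly zero for identical logits.

## Synthetic lodged-field data

`generate_field()` builds a mosaic whose index mask is exact ground truth
by construction: textures are applied strictly within mask regions.

* **Lodging geometry.** The lodging mask is the upper level set of a
  smooth random field (a coarse Gaussian grid with correlation length
  `patch_scale`, bilinearly upsampled), thresholded at the quantile that
  realises the configured cover — default **0.42** of all pixels, a
  heavily lodged paddy — exactly up to rounding. This yields smooth,
  irregular patches resembling real lodging.
* **Appearance.** Healthy canopy: darker green with strong narrow
  planting-row stripes. Lodging: slightly brighter/yellower with broader,
  fainter stripes at a different angle. The colour means are deliberately
  close (the green-channel separation is about 0.04), so texture and
  context, not colour alone, must carry the classification. A small
  fraction of pixels (default 4%) is bare path. Per-pixel Gaussian noise
  (sd 0.02) is added, and the image is quantised to 8 bits so PNG round
  trips are exact.
* **What it does not emulate.** Perspective and stitching artefacts,
  shadows, specular water, growth-stage gradients, class-boundary
  mixed pixels, and the sheer scale of real orthomosaics. Tests passing
  on this generator demonstrate that the machinery is correct and that
  the methods behave directionally as expected on a texture-separable
  two-vegetation-class problem; they do not certify field accuracy.

The tiling protocol mirrors orthomosaic practice: contiguous spatial
bands split the mosaic 60/20/20 into train/val/test regions (bands keep
the leakage-free disjointness property; the authors' actual spatial
layout of their split is not public), evaluation tiles are sampled
without overlap inside their band by bounded rejection sampling, and
training tiles are sampled freely inside the training band only. The
default mosaic is 1536×1536 with 64-pixel tiles, 200 training and 100
evaluation crops: with 0.2-ratio bands, a 1536-wide mosaic leaves a
307-pixel band holding 50 disjoint 64-pixel tiles at about 43% packing
density, comfortably below the random-packing jamming limit — at
1024×1024 the same 50 tiles would not fit disjointly. The full-scale
protocol (224-pixel tiles, 2000/9000 crops) is available through the same
configuration objects.

## Training schedule

The transfer-learning schedule is: freeze the backbone for the first 20
of 40 epochs (decoder-only updates, batch 16), then unfreeze everything
(batch 4); learning rate $5\times10^{-4}$ multiplied by 0.92 every epoch.
Those are the package defaults in `train_config()`. The optimiser behind
the schedule is not pinned down by the method; the default here is
RMSprop (momentum-free adaptive scaling), with plain SGD selectable. The
best checkpoint is the highest validation mIoU, ties to the earlier
epoch. Training is single-threaded and fully deterministic given the
seed.

## The desk benchmark

`run_desk_benchmark()` fixes one synthetic study at desk scale: 1536²
mosaic with 42% lodging, 200 training / 50 validation / 50 test tiles of
64 px, and 10 epochs of from-scratch training. Because the tiny models
start from random weights rather than a pretrained backbone, the
benchmark uses `freeze_epochs = 0`, batch 8, and a higher initial rate
($2\times10^{-3}$) than the transfer-learning default — at $5\times10^{-4}$
and 250 optimiser steps, all variants underfit to the class prior and no
comparison is meaningful. Augmentation is off so all variants see
identical batches per seed, and all variants train with inverse-frequency
class weights in the CE loss: the bare-path class covers only ~4% of
pixels and an unweighted loss gives the small networks almost no signal
to learn it. Three training seeds are run per variant on the shared
dataset; the teacher (twice as wide and deep) is trained once. The
benchmark's claim is directional — attention-augmented ≥ baseline and
distilled ≥ baseline in mean validation mIoU, by margins exceeding the
across-seed standard deviation — mirroring the qualitative ordering
reported for full-scale UAV studies without attempting their absolute
numbers, which require GPU training on the original (non-public) datasets
with pretrained full-size backbones.

The attention student of the benchmark inserts the block only in the
final encoder block (the 8×8 grid, where the $(HW)^2$ affinity is cheap
and activations are moderate), uses embedding width 16, the
`identity_start` initialisation, the $1/\sqrt{C'}$ affinity scaling, and
a 0.3 learning-rate multiplier on attention parameters
(`attn_lr_scale`). Each of these choices came out of pilot runs on
training *stability*: insertion at the 16×16 stage or full-rate updates
of the attention branch can blow up its output scale mid-run (the raw
affinity chains three learned matrix products, so its scale reacts
sharply to weight changes), and default-initialised attention delays the
escape from the class-prior plateau by several epochs.

One property of this regime deserves honesty: at desk scale the
attention gain is **bimodal**. A run either discovers the global-context
solution — jumping substantially, mostly by finally learning the rare
background class, which plain convolutional students essentially never
learn here — or it stays at the conv-only plateau. The
mean gain across seeds is substantial, but the across-seed standard
deviation is inflated by this all-or-nothing activation, so the
margin-beyond-SD check at three seeds depends on which seeds activate;
the corresponding acceptance test documents this rather than hiding it.
Knowledge distillation from the (class-weighted, wider, deeper) teacher
is the more reliable of the two effects at this scale: the teacher's
soft channel distributions transmit where it sees each class, including
the rare one, and the student's gain is smoother across seeds. On real
imagery with pretrained full-size backbones, attention fine-tuning does
not face this from-scratch activation lottery.

Numerical choices worth knowing: convolutions use zero "same" padding at
any atrous rate; bilinear resampling is corner-aligned and its gradient
is the exact adjoint; the cross-entropy and channel softmaxes subtract
the row maximum before exponentiation; gradients flow through every path
of the attention block (verified against finite differences); and
confusion-matrix classes with an empty union are excluded from the mIoU
mean rather than scored, with `include_background` selectable.

## Limitations

* Pure-R/Armadillo training is CPU-bound; the package is a faithful,
  testable implementation of the methods at desk scale, not a production
  trainer for megapixel mosaics.
* No batch normalisation: the compact models rely on input centring and
  fan-based initialisation, which is adequate at these widths but would
  not scale to deep backbones.
* ImageNet/VOC pretraining is out of scope; `load_pretrained()` defines
  the checkpoint contract only.
* The synthetic generator's realism limits are listed above; absolute
  mIoU values on it should not be compared against field studies.
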