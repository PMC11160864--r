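---
title: "Hierarchical layer-selective feedback distillation: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical layer-selective feedback distillation: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Compact segmentation networks are attractive for deployment on modest
hardware, but trained alone they fall well short of large encoder-decoder
models on tasks such as kidney and liver tumor segmentation in CT. Knowledge
distillation (KD) narrows the gap by letting a small *student* network mimic
a large pretrained *teacher*. Classic KD supervises only the student's
output; the signal attenuates through backpropagation, and the shallow
student layers accumulate training bias. Hint-style methods that pair layers
one-to-one capture only what each matched layer knows.

This package implements a layer-selective *feedback* scheme: knowledge flows
backwards across depth, from a fused representation of the teacher's middle
layers into the student's *early* layer, and from the teacher's *terminal*
layer into each student *middle* layer — at both the feature level and the
pixel level — so early student layers see global, task-relevant structure
from the start.

## Losses

Let $z^s_{\text{early}}, z^s_{\text{mid}_j}, z^s_{\text{late}}$ and their
teacher counterparts be encoder activations tapped at the first, the
intermediate, and the last encoder stage. The attention operator
$\mathcal{A}(z)$ aggregates absolute activations across channels,
$a_{hw} = \sum_c |z_{chw}|^p$ (default $p = 1$), rescales the map
bilinearly to the comparison grid, flattens, and L2-normalises with an
$\varepsilon$-guard. Feature-level distillation uses

$$
\mathcal{L}_{\mathrm{UFD}} = \left\lVert
  \hat{\mathcal{A}}(z^s_{\text{early}}) - \hat{\mathcal{A}}(z^t_{\text{mid}})
\right\rVert_2, \qquad
\mathcal{L}_{\mathrm{IFD}} = \sum_{j=1}^{N} \left\lVert
  \hat{\mathcal{A}}(z^s_{\text{mid}_j}) - \hat{\mathcal{A}}(z^t_{\text{late}})
\right\rVert_2,
$$

where $z^t_{\text{mid}}$ is the *unified middle representation*: every
teacher middle map resampled to the smallest middle grid and concatenated
along channels, with attention computed on the concatenation. The published
formulation's typography (norms of normalised norms) is ambiguous; the
attention-transfer reading above — unit vectors compared in L2 — is the only
one consistent with "channel normalisation" yielding a scalar loss, and is
what the package implements (an L1 difference is available via
`hlfd_control(norm = "L1")`).

At the pixel level, the teacher's deep-supervised decoder emits predictive
maps at every scale. With $p^t_{\text{mid}}$ the per-pixel average of the
teacher's middle predictive maps (renormalised on the simplex) and
$p^t_{\text{late}}$ its terminal map,

$$
\mathcal{L}_{\mathrm{UPD}} = \mathrm{KL}\!\left(p^s_{\text{early}} \,\middle\|\, p^t_{\text{mid}}\right), \qquad
\mathcal{L}_{\mathrm{IPD}} = \frac{1}{N}\sum_{j=1}^{N}
  \mathrm{KL}\!\left(p^s_{\text{mid}_j} \,\middle\|\, p^t_{\text{late}}\right),
$$

where the student maps come from 1x1 auxiliary class heads on its encoder
taps, spatially rescaled to the teacher map's grid and softmaxed. Note the
deliberate asymmetry — the feature-level individual loss *sums* over layers
while the pixel-level one *averages* — and the KL direction, student
distribution first, exactly as the scheme is written (the classic
teacher-first direction is available via `hlfd_control(kl_direction =
"teacher_first")`). KL is computed in nats with $10^{-8}$ smoothing inside
the log ratio and averaged over pixels, so values are
resolution-independent.

The full objective is
$$
\mathcal{L} = \mathcal{L}_{\mathrm{seg}}
  + \beta\,(\mathcal{L}_{\mathrm{UFD}} + \mathcal{L}_{\mathrm{IFD}})
  + \lambda\,(\mathcal{L}_{\mathrm{UPD}} + \mathcal{L}_{\mathrm{IPD}}),
$$
with defaults $\beta = 0.9$, $\lambda = 0.1$ — the best setting in the
method's sensitivity analysis, which also found that keeping
$\beta > \lambda$ (feature-level dominant) matters. $\beta = \lambda = 0$
reduces the trainer exactly to supervised segmentation, a property pinned by
a test.

$\mathcal{L}_{\mathrm{seg}}$ is a focal-dice loss. The name fixes neither
formula; this package uses the most common composition, a sum of focal
cross-entropy $-\frac{1}{HW}\sum (1-p_{\text{true}})^\gamma \log
p_{\text{true}}$ with $\gamma = 2$ and soft dice
$1 - (2\sum p_{\text{fg}} g + \epsilon)/(\sum p_{\text{fg}} + \sum g +
\epsilon)$ with $\epsilon = 1$; both constants are exposed in
`loss_weights()`. The exact composition does not interact with the
distillation machinery, which is what the package is about.

## Reference networks

No deep-learning framework is available to R in this package's dependency
footprint, so the package carries its own minimal reverse-mode
differentiation tape with Rcpp/Armadillo convolution kernels (im2col + GEMM).
Every operator's backward pass is checked against central finite differences
in the test suite, and whole-graph gradients are spot-checked the same way.
This bounds network sizes to CPU scale, which drives several choices below.

The *teacher* is a compact encoder-decoder: four encoder stages (default
widths 8/16/32/64, stride-2 between stages), a decoder that upsamples,
concatenates the same-scale encoder feature (long skip connections) and
convolves at half the encoder width, and 1x1 deep-supervision heads at every
decoder scale plus the bottleneck. A fully nested (dense-skip) decoder was
considered and rejected: at these widths nesting roughly doubles decoder
cost without touching any distilled quantity. The predictive-map bundle
names its taps by scale, mirroring the encoder trichotomy: the full-resolution
head is the `early` map (and the teacher's segmentation output), the 32x32
and 16x16 heads are the `mids`, and the bottleneck head is the `late` map.
Only the unified `mids` and the `late` map enter the distillation losses, so
this naming convention carries no modelling weight.

The *student* is a residual-block encoder (default widths 6/12/24/48; about
45k parameters against the teacher's 90k) with a deliberately light
upsampling head — 1x1 bottleneck projection, one 3x3 refinement at double
resolution, bilinear upsampling to full resolution, 1x1 class head. How a
plain classification-style encoder should produce full-resolution
segmentation is left open by the method; a naive upsampling head is the
weakest reasonable choice and therefore the most honest baseline for
measuring what distillation adds. The auxiliary maps are 1x1 class
projections on the early and middle encoder taps, trained *only* by the
pixel-level losses and stripped by `export_for_inference()`; a test verifies
the final output is bit-identical with and without them.

Class-head biases are initialised to foreground prior log-odds (-2.5, about
8% foreground) rather than zero. With rare foreground, a zero-initialised
network spends much of its training escaping the all-background regime; the
prior initialisation removes that transient. All other weights are He-scaled
normal draws, bit-reproducible from the build seed.

During distillation the teacher is frozen: its parameters enter the
computation graph as constants, so no gradient can reach them — the freeze
contract is structural, not an optimiser flag — and a test asserts teacher
parameters are bit-identical after training while every loss component alone
produces nonzero student gradients.

## Synthetic phantoms

The generator emulates windowed abdominal CT slices well enough to exercise
every pipeline component without any data download: one elliptical organ per
slice (kidney tissue 25-40 HU, liver 45-60 HU), zero to three hypodense
tumor blobs with irregular radially-perturbed boundaries (radius 25-50% of
the organ's minor semi-axis), a smooth background texture around -80 HU, and
additive Gaussian noise. Tumor count has P(0) = 0.15, so about 85% of slices
contain foreground. `difficulty` sets the tumor/organ contrast and noise:
easy is 60 HU contrast with 5 HU noise, hard is 25 HU with 10 HU — values
chosen once as plausible for enhancing vs. subtle lesions within the organ
windows (kidney -200..300 HU, liver -40..160 HU), so windowed images retain
usable contrast. Augmentation is restricted to 90-degree rotations and
flips, applied identically to image and mask, keeping masks exactly binary;
additive-noise augmentation is deliberately not offered (it is a poor match
for CT noise statistics).

What the phantoms do *not* model: 3-D anatomy, partial-volume effects,
scanner reconstruction artefacts, multiple organs, or the intensity
statistics of any real dataset. Passing tests therefore demonstrate that the
distillation machinery behaves as specified and that its benefit is
measurable on a controlled task — not that any particular Dice level
transfers to real CT.

## Training protocol and problem sizes

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with per-epoch cosine annealing
from $10^{-3}$ to $10^{-6}$, batch size 8, seed-stable 80:20
train/validation split. The packaged experiment — also what
`scripts/acceptance.R` reruns — uses 250 hard kidney phantoms at 64x64
(200 train / 50 validation), 20 teacher epochs, and three student runs per
arm (seeds offset 0/1/2) of 10 epochs each, reported as mean over seeds:
sizes chosen so the whole study runs in minutes on one CPU core while still
separating the arms. The teacher is pretrained with the focal-dice loss on
the final head and every deep-supervision head (masks nearest-neighbour
downsampled to each head's grid; the final full-resolution head carries
weight 0.6 and the deep-supervision heads share 0.4, since final-map
boundary quality dominates Dice), and must reach validation
Dice at least 0.85 before being used to distill.

Evaluation thresholds foreground probability at 0.5. Dice uses the both-empty
convention (score 1); the relative volume difference
$(\lvert P\rvert - \lvert G\rvert)/\lvert G\rvert$ keeps its sign per sample,
is undefined (excluded, logged) for empty ground truth, and is aggregated as
mean absolute value when ranking.

## Numerical choices

- Bilinear resampling everywhere, half-pixel-centre convention, which
  preserves constants and is exactly linear (its adjoint is used in
  backprop and tested via inner-product identity).
- Attention normalisation guard $\varepsilon = 10^{-8}$: an all-zero
  feature map yields a zero attention vector, and two zero maps give loss 0.
- KL smoothing $10^{-8}$; softmax temperature fixed at 1 (exposed in
  `hlfd_control()` but unexplored here, as no temperature is part of the
  method).
- The unified teacher middle *probability* map is an average (then simplex
  renormalisation), not a concatenation: class maps must stay class maps.
  A product-of-experts pool would also be type-valid but sharpens the
  teacher's uncertainty, which the losses give no licence for.
- UPD/IPD compare at the teacher map's resolution, mirroring the
  feature-level rescaling direction (student rescaled to teacher grid).

## Known limitations

- Gradients flow through a single-threaded R/Rcpp engine; networks beyond a
  few hundred thousand parameters or inputs beyond 128x128 become slow.
- The phantom study is directional: it shows the hierarchical feedback
  objective not hurting and typically helping a capacity-limited student,
  not the double-digit gains reported on real CT benchmarks at full scale.
- 2-D slices only; the dice/focal losses assume a binary foreground.
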