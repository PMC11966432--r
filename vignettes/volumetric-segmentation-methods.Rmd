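---
title: "Attention-gated V-Net with deep supervision: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated V-Net with deep supervision: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnetseg)
```

## The segmentation problem

Uterine fibroids on T2-weighted pelvic MRI are a demanding segmentation
target: the lesions are small relative to the field of view (often well
under 5% of the voxels), their contrast against surrounding myometrium is
low, their number, size and position vary from patient to patient, and the
acquisition is strongly anisotropic — sub-millimetre in-plane resolution
against slices several millimetres thick. Accurate delineation matters
clinically because focused-ultrasound ablation is planned directly on the
segmented volume.

`vnetseg` implements a fully three-dimensional approach: a V-Net style
encoder–decoder operating on whole volumes, with two additions aimed at
exactly the failure modes above — *attention gates* on the skip connections,
which learn to suppress irrelevant background in the encoder features before
they are fused into the decoder, and *deep supervision*, which attaches
auxiliary loss heads to intermediate decoder stages so that gradient reaches
the deep layers directly and the network cannot collapse onto the trivial
all-background solution that a 98%-background class balance invites.

## Architecture

The encoder has five stages at channel widths 16, 32, 64, 128, 256. Each
stage is a block of $3^3$ convolutions (counts per stage configurable as a
nine-element tuple over 4 encoder stages, the bottom stage and 4 decoder
stages; default `(1,2,3,3,2,2,2,2,2)`), each convolution followed by a
PReLU activation, an instance normalisation and dropout at rate 0.01.
Stages are joined by stride-2 convolutions, so a 128×128×48 input descends
through 64×64×24, 32×32×12 and 16×16×6 to an 8×8×3 bottom at 256 channels.
Each stage keeps the V-Net residual connection (element-wise addition of the
stage input, via a 1×1×1 projection when channel counts differ); the
connection is toggleable because its presence is an architectural choice
rather than something the stage table fixes.

The decoder mirrors the encoder with stride-2 transposed convolutions
(kernel equal to the convolution kernel, padding chosen so sizes exactly
double), concatenating the attention-gated encoder skip after each
upsampling and finishing with a full-resolution stage at width 16 and a
1×1×1 projection to two class logits, softmaxed per voxel.

**Attention gates.** For a skip map $x^l$ and the coarser gating signal $g$
from one level deeper, both are projected by 1×1×1 convolutions to a joint
width (half the skip channels by default; the skip projection uses stride 2
so both live on $g$'s grid), added, passed through ReLU, projected to one
channel, and squashed by a sigmoid into a coefficient map
$\alpha \in (0,1)$. $\alpha$ is resampled trilinearly back to the skip grid
and multiplies $x^l$ channel-wise. Zero weights therefore give
$\alpha \equiv 0.5$ — the gate at initialisation passes half the signal
rather than none of it.

**Deep supervision.** Decoder stages at 1/8, 1/4 and 1/2 resolution (the
set is configurable) carry heads of repeated stride-2 transposed
convolutions — one per factor of two, halving channels — followed by a
1×1×1 projection and a softmax, yielding full-size auxiliary probability
maps. The training objective is

$$L \;=\; L_{\text{main}} \;+\; \sum_{m \in M} \eta_m\, L_m, \qquad
\eta_m(e) = \eta_m(0)\,\gamma_\eta^{\,e},$$

with $\eta(0) = (0.5, 0.25, 0.125)$ from deepest to shallowest and
$\gamma_\eta = 0.99$ per epoch, so the auxiliary pressure fades as training
matures. The decay schedule and the membership of $M$ are genuinely open
design points (neither is pinned down by the stage table); both defaults are
stated here once and exposed in `deep_supervision_spec()`.

## Objective

The main and branch losses default to the squared-denominator soft Dice

$$L_{\text{Dice}} = 1 - \frac{2\sum_i p_i g_i + s}{\sum_i p_i^2 + \sum_i g_i^2 + s},
\qquad s = 10^{-5},$$

the overlap objective of choice when the foreground occupies a tiny volume
fraction: its gradient is normalised by the object size rather than the
image size. A per-voxel negative log-likelihood is also provided (and may
be combined with Dice); it uses the *mean* over voxels rather than a sum so
that its magnitude — and hence the meaning of the $\eta_m$ defaults — is
independent of crop size. The softmax is stabilised by per-voxel max
subtraction, and the NLL floors probabilities at $10^{-12}$.

## Training recipe

Adam with first-moment decay 0.9 ("momentum" in optimiser shorthand),
initial learning rate $2\times 10^{-4}$ decaying exponentially by 0.999 per
epoch, batch size 1 (whole volumes are memory-hungry; the normalisation is
instance-style precisely so that batch-1 training is well defined), Dice
objective, 600 epochs at full scale. Desk-scale runs use the same recipe
with fewer epochs. The best checkpoint is selected by mean validation DSC
— a selection criterion this package fixes explicitly since nothing in the
recipe pins it down.

One deliberate deviation for the *smoke-scale* overfit check (one phantom,
the `tiny_network_config()` at channels 4–32 on a 32×32×16 grid): the
learning rate is raised to $10^{-3}$. The $2\times10^{-4}$ schedule is
tuned for hundreds of epochs over hundreds of cases; a 300–500-step
single-case overfit is a different optimisation problem, and the larger
step size is the appropriate desk-scale analogue. With it, the tiny model
passes train DSC 0.9 in roughly 200–300 steps on one CPU.

Data splitting is a seeded shuffle with floor allocation and remainders
granted to training: 245 cases at ratio 6:2:2 give exactly 147 training,
49 validation and 49 test cases. We use "validation" for the model-selection
partition and "test" for the held-out reporting partition throughout.

## Preprocessing

The pipeline runs normalise → resample → pad/crop, with noise augmentation
last and train-time only:

* **Normalisation** is per-volume (z-score to mean 0, population sd 1, or
  min–max to $[0,1]$). Whether cohort-level normalisation was ever meant is
  ambiguous; per-volume is the robust choice when scanner scaling varies,
  and it is what the constant-volume degenerate rule (map to zeros) is
  defined for.
* **Resampling** maps to a target physical spacing with the shape rule
  `round(shape · spacing / target)` per axis (minimum 1); images
  trilinearly, masks by nearest neighbour so they stay binary. The default
  for phantom work is `"keep"` (no resampling) since phantoms are generated
  on the target grid; for heterogeneous real data a fixed spacing should be
  configured — no canonical value is assumed.
* **Pad/crop** centres the content on the fixed network grid (default
  128×128×48, every axis divisible by 16 so four stride-2 stages divide
  evenly), padding with 0 — approximately the background mean after
  z-scoring — with the odd voxel going to (padding) or coming from
  (cropping) the high side.
* **Noise augmentation** is additive zero-mean Gaussian, default sd 0.05 in
  normalised units; "random noise" admits many readings and this is the
  simplest that exercises robustness to acquisition noise.

## Evaluation metrics

From voxel confusion counts: DSC $= 2TP/(2TP+FP+FN)$, IOU
$= TP/(TP+FP+FN)$, sensitivity $= TP/(TP+FN)$ and precision
$= TP/(TP+FP)$. Degenerate cases are resolved explicitly rather than left
to division by zero: both masks empty gives DSC = IOU = 1 with a
`both-empty` flag; an empty prediction against a nonempty reference gives 0;
sensitivity and precision return `NA` when their denominators vanish, and
aggregation excludes `NA`s while reporting how many were excluded.

The Hausdorff distance is the exact symmetric max–min over *all* foreground
voxel centres, with coordinates scaled by the voxel spacing so the result is
in millimetres (at 6 mm slices the anisotropy matters). It is computed with
an exact anisotropic Euclidean distance transform (lower envelope of
parabolas, one pass per axis) and cross-checked in the test suite against
exhaustive pairwise distances to $10^{-9}$ on hundreds of random masks.
Boundary-only and full-set HD coincide for the farthest-point terms in
typical solid masks but not in all cases; full-set semantics is what is
implemented and tested. No 95th-percentile variant is offered. HD is
refused (and reported `NA` with a flag) when either mask is empty.

Argmax ties at probability 0.5 are assigned to *background*: a conservative
rule, stated because it changes the confusion counts.

## The phantom generator

`generate_phantom()` emulates the statistical character of the clinical
data, not its anatomy: a smooth low-frequency background field (coarse
Gaussian grid, trilinearly upsampled), a brighter uterus-like ellipsoid,
and 1–3 randomly oriented ellipsoidal lesions placed inside it, rendered as
an exact intensity offset of $-0.25$ (hypointense, as fibroids typically
are on T2) with Gaussian noise of sd 0.05 on top. Default spacing is
0.76×0.76×6 mm — the fine-in-plane/thick-slice geometry of a 512-matrix
pelvic protocol — which forces every spacing-aware code path (resampling,
millimetre HD) through nontrivial branches. Lesion semi-axes are drawn from
5–25 mm, the total analytic lesion volume is capped at 5% of the volume to
preserve the class-imbalance regime, and lesions keep a 2-voxel margin from
the border. Per-case seeds are `seed + index`, so datasets are reproducible
and extendable.

What phantoms do *not* model: MRI physics (no bias fields, no sequence
contrast mechanisms), anatomical shape complexity, and inter-patient
intensity nonstationarity. Passing tests on phantoms therefore demonstrate
that the architecture, objective, optimiser and metrics are implemented
correctly and can fit structure in low-contrast anisotropic volumes — they
say nothing about clinical-grade accuracy, which requires real cohorts and
full-scale training.

## Numerical choices and degenerate inputs

* Convolution, transposed convolution, trilinear resampling and the
  distance transform are native kernels; all gradients (including the
  attention-gate path and instance norm) are verified against central
  finite differences in the test suite.
* Instance norm uses $\varepsilon = 10^{-5}$; z-scoring guards
  $\sigma < 10^{-8}$ by mapping to zeros.
* Transposed convolutions use the convolution kernel size with padding
  $(k-1)/2$ and implicit output padding 1, so each decoder step exactly
  doubles each axis and shape algebra inverts the encoder without
  special cases.
* Weight initialisation is He-scaled Gaussian by fan-in, PReLU slopes start
  at 0.25, norm scales at 1; all randomness flows through a single integer
  seed, and helpers preserve the caller's RNG state.
* Desk-scale problem sizes used throughout the tests and the acceptance
  script: 32×32×16 grids, channels 4–32, up to a few hundred optimizer
  steps, four-case end-to-end runs.

## Known limitations

Single-channel input and binary segmentation only; batch parallelism and
accelerators are out of scope (training is CPU-bound and intended for
desk-scale experiments); no DICOM ingestion (NIfTI only — the on-disk
format is this package's choice); checkpoint files are R serialisations,
not interchange formats; and the attention-gate internal width and the
deep-supervision head widths are heuristics (half the skip/stage channels)
rather than tuned values.
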