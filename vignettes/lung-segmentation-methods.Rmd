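---
title: "Lung CT segmentation: models, parameters and design choices"
author: "ResBCDUNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung CT segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ResBCDUNet)
```

# Overview

ResBCDUNet segments lung parenchyma in 2-D CT slices. The pipeline has
three stages: (1) semi-automatic ground-truth extraction from
Hounsfield-unit (HU) images by thresholding and binary morphology, (2)
engineering of a three-channel network input from each slice, and (3) a
U-shaped deep network — ResNet-34 encoder, densely connected bottleneck,
bidirectional convolutional-LSTM (BConvLSTM) skip fusion — trained by
backpropagation, followed by pixel-level evaluation. This vignette
explains each model, its assumptions, the tunable parameters, and the
numerical and design choices that were genuinely open.

# Ground-truth extraction

CT attenuation is calibrated: air ≈ −1000 HU, aerated lung ≈ −800 HU,
water = 0 HU, soft tissue ≈ +40 HU. A threshold of −604 HU separates lung
parenchyma from the chest wall; the mask is 1 where `f(i,j) < T` (strict
inequality, so a pixel exactly at −604 HU is background). The seven-step
pipeline (`extractLungMask()`) is:

1. threshold at −604 HU — lungs *and* the surrounding air become
   foreground;
2. clear border-connected blobs — the surrounding air always touches the
   frame, the lungs never do;
3. label connected components (8-connectivity);
4. keep the two largest components — the lungs;
5. erode with a disk of radius 2 — separates vessels from wall-attached
   structure;
6. close with a disk of radius 10 — re-attaches juxtapleural nodules,
   which thresholding carves out of the lung field because their HU is
   above the threshold;
7. fill enclosed holes (4-connected background) — intra-lung vessels.

Assumptions: one axial slice with two lung fields that do not touch the
image border; HU calibration; nodule bites no wider than the closing
disk. A slice violating these (e.g. uniform air) yields an empty mask that
is *flagged for manual review* (`attr(mask, "needsReview")`), not an
error — failed extractions are expected occasionally and are reviewed by a
human in the intended workflow.

**Numerical conventions.** The structuring element is the discrete
Euclidean disk `{(dx,dy): dx²+dy² ≤ r²}`. Erosion treats out-of-frame
pixels as background. Closing is composed on a canvas padded by the disk
radius, so the intermediate dilation may extend past the frame before
being eroded back: this is the infinite-plane set definition cropped to
the frame, and it is what makes closing extensive and idempotent near the
border (a plain erode-after-dilate inside the frame is not). Labelling and
border clearing use 8-connectivity; hole filling floods the background
with 4-connectivity — the standard complementary pair that prevents
diagonal leaks from holes to the border. Both connectivities, the
threshold, the disk radii and the number of kept components are exposed in
`maskPipelineParams()`. Area ties in "keep the two largest" break toward
the smaller (scan-ordered) label, which makes the pipeline a pure
function.

# Channel engineering

Each slice becomes an H×W×3 stack in [0, 1] (`assembleChannels()`):

* **channel 1** — the original image, min–max normalized over a clipping
  window of [−1000, 400] HU. This is a standard lung window; the
  normalization scheme is the package's choice.
* **channel 2** — a Canny edge map: Gaussian smoothing (σ = 2 by
  default), Sobel gradients, non-maximum suppression along the quantized
  gradient direction, and double-threshold hysteresis. Hysteresis
  thresholds default to the 70th/90th percentiles of the non-zero gradient
  magnitude, making them contrast-invariant; absolute thresholds can be
  given instead. All Canny parameters were open design choices and are
  exposed in `channelParams()`.
* **channel 3** — the binary image at the same −604 HU threshold but with
  inverted polarity (lung black = 0, background white = 1), dilated with a
  disk of radius 2: white grows, removing black noise specks and
  tightening the white rim around the lungs. The radius is again an open
  choice, default 2, configurable.

`assembleChannels(..., defaultChannels = TRUE)` replicates the normalized
original into all three channels; this is the default-channel ablation
arm, and it runs through the identical downstream pipeline.

# The segmentation network

`buildModel()` constructs the network from a `NetworkConfig`:

* **Encoder** — ResNet-34: a 7×7 stride-2 stem convolution (64 channels at
  full width), 3×3 stride-2 max-pool, then four stages of 3/4/6/3 basic
  residual blocks with widths 64→128→256→512, doubling at each stride-2
  stage transition (1×1 projection on the shortcut there, identity
  elsewhere).
* **Bottleneck** — 3 convolutional blocks at the deepest resolution whose
  inputs *concatenate* all previous block outputs (2 dense connections);
  features are combined by concatenation, never summation, to avoid
  relearning redundant features. With `useDenseBottleneck = FALSE` the
  blocks stack plainly.
* **Decoder** — five ×2 nearest-neighbour up-samplings. The stem performs
  five halvings in total, hence five up-samplings; the four *named* skip
  levels (widths 64/128/256/512) are fused with BConvLSTM, the deepest of
  them at equal resolution with the bottleneck output, and the stem-level
  connection is a plain concatenation. Each up-conv block is
  upsample → 3×3 convolution → normalization → ReLU, so normalization
  follows every up-sampling. After each fusion, two 3×3
  convolution–normalization–ReLU blocks restore the level's width. A 1×1
  convolution and sigmoid produce the per-pixel probability.
* **BConvLSTM fusion** (`bconvlstmFuse()`) — the encoder and decoder maps
  form a length-2 sequence; one convolutional LSTM processes it as
  (encoder, decoder), a second independent one processes the reversed
  order, and the two final hidden states are concatenated. Gate order is
  (input, forget, output, candidate); the hidden width equals the level
  width; the kernel is 3×3 — both are the customary bidirectional
  ConvLSTM choices, fixed here as package defaults. With
  `useBConvLSTM = FALSE` fusion degrades to plain concatenation with the
  same channel count, so the two ablation arms are architecturally
  comparable.

**Implementation.** All layers, including their backward passes, are
written in the package: convolutions run as im2col (C++) plus BLAS GEMM,
and the full backward pass is verified against central finite differences
in development. Normalization layers use per-sample spatial statistics
with running moments for inference (training processes samples in a
streaming loop); this is the package's numerical choice for the
normalization layers of the decoder and encoder blocks.

**Training** (`trainModel()`): Adam (β₁ = 0.9, β₂ = 0.999), default
learning rate 1e-4, binary cross-entropy loss by default with soft-Dice
and BCE+Dice selectable — loss and optimizer were open choices.
Initialization is seeded He-normal with normalization scales 1 and a
ConvLSTM forget-gate bias of 1. Every stochastic choice (initialization,
shuffling) derives from the seed, so runs are reproducible to
floating-point determinism of the BLAS. Probabilities are clipped to
[1e-7, 1−1e-7] inside the loss; a non-finite loss aborts with a
diagnostic. `earlyStopDice` stops training at the first epoch whose
validation Dice reaches the requested level. Pre-trained encoder weights
are load-only from an explicit file; nothing is ever downloaded, and
random initialization is the self-contained default.

# The phantom simulator

`generatePhantom()` renders what the extraction and the network assume: an
air background (−1000 HU), a soft-tissue body ellipse (+40 HU), two dark
lung ellipses (−800 HU, safely below the −604 HU threshold), bright
intra-lung vessel disks (0 HU), and optionally a juxtapleural nodule
(+20 HU) centred radius+4 px inside the lateral lung wall. At that depth
the nodule sits against the wall within the morphological working band:
the radius-2 erosion opens its thresholding bite to the wall, so only the
radius-10 closing can recover it — the regime the closing step exists
for — while every nodule pixel remains recoverable. Ground truth is the
filled lung ellipses plus the nodule disk, known exactly by construction.

Defaults: 256×256 frame, Gaussian HU noise with sd 20 (an order of
magnitude below the 196 HU gap between lung and threshold, so the
threshold regime stays realistic but solvable), 6 vessels.
`generateCohort()` jitters ellipse centres/axes and nodule placement per
sample, with per-sample seeds derived deterministically from the cohort
seed (the first sample reproduces `generatePhantom(spec)` exactly, so a
degenerate cohort is the single phantom).

What the phantom does *not* emulate: soft-tissue texture, partial-volume
boundary gradients, scanner reconstruction artefacts, pathology other
than a single nodule, and anatomical shape variation beyond ellipse
jitter. Tests passing on phantoms therefore demonstrate that the
operators, the extraction pipeline and the learning machinery are
implemented correctly and that the network can fit separable data — not
that clinical-grade Dice scores transfer to real archives, which require
full-scale images, curated masks and far longer training.

# Evaluation

Positive class = lung = 1 (the raster convention writes lung as 255).
`confusionCounts()`/`pixelMetrics()` implement accuracy, precision,
recall and F1 with an explicit `NA` marker for 0/0 cases.
`diceCoef()` is 2|E∩Q|/(|E|+|Q|); two empty masks score 1 (perfect
agreement on emptiness — a convention this package fixes). Dice equals F1 for the same positive class, and the test
suite asserts the identity on random masks. `rocAuc()` pools all pixels,
sweeps every distinct threshold and integrates trapezoidally; it equals
the Mann–Whitney concordance statistic, which the tests verify against a
brute-force pairwise count. Metrics are pooled over the dataset (one
confusion matrix), matching a dataset-level confusion analysis; a
per-image table is available via `evaluateMasks(..., perImage = TRUE)`.

# Problem sizes used in tests

The test and acceptance workloads are desk-scale by design: morphology
oracles run on ≤ 20×20 masks (200 random draws); ground-truth recovery on
fifty 256×256 phantoms spanning noise sd 0–20 HU; the architecture
contract at the full 256×256 input with the full 64–512 channel schedule;
learnability at 64×64 with `baseFilters = 8` (the proportionally narrowed
schedule 8–64) on 40 training phantoms, which a correct implementation
fits to held-out Dice ≥ 0.90 within a handful of epochs. Width is a
scaling knob, not part of the contract: the channel-doubling invariant and
the block structure are identical at every width.

# Known limitations

* Single-slice (2-D) processing only; no volumetric context.
* The DICOM reader supports uncompressed little-endian single-frame files
  (explicit or implicit VR) — sufficient for standard CT archives and the
  package's fixture writer, but not compressed transfer syntaxes.
* Per-sample normalization statistics differ from cross-batch statistics;
  with batch training of heterogeneous images the running moments converge
  similarly, but exact parity with a batch-statistics implementation is
  not claimed.
* Training is CPU-bound R/BLAS; it is meant for verification and
  small-scale experiments, not for full 512×512 clinical training runs.
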