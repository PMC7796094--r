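# ResBCDUNet

Lung parenchyma segmentation for 2-D CT slices, end to end: semi-automatic
ground-truth extraction by Hounsfield-unit thresholding and binary
morphology, engineered three-channel network inputs, a U-shaped
segmentation network with a ResNet-34 encoder, densely connected bottleneck
and bidirectional convolutional-LSTM (BConvLSTM) skip fusion, and
pixel-level evaluation. A deterministic lung-phantom simulator with exactly
known ground truth makes every stage testable on a desk machine, without
access to a clinical archive or a GPU.

The package is aimed at medical-image-analysis researchers who want a
fully inspectable, dependency-light reference implementation of this
segmentation pipeline in R: every operator down to the convolutions and
their backward passes is in the package, with brute-force oracles in the
test suite.

## The method

**Ground-truth extraction.** A CT slice `f(i,j)` in HU is thresholded at
T = −604 HU (between aerated lung ≈ −800 HU and soft tissue ≈ +40 HU):

    Binary(i,j) = 1  if f(i,j) < T,  else 0

followed by six morphological steps: clear border-connected blobs (the
surrounding air), label connected components, keep the two largest (the
lungs), erode with a disk of radius 2, close with a disk of radius 10
(recovers juxtapleural nodules carved out by thresholding), and fill
enclosed holes (vessels). Masks use foreground = lung = 1 (255 in BMP/PNG
rasters).

**Input engineering.** Each slice becomes an H×W×3 stack: (1) the original
image min–max normalized over a [−1000, 400] HU lung window, (2) a Canny
edge map, (3) the dilated binary image (lung black, dilated white
background; disk radius 2).

**Network.** A U-shaped encoder–decoder. The encoder is ResNet-34
(7×7/stride-2 stem, 3×3/stride-2 max-pool, then 3/4/6/3 basic residual
blocks with channel widths 64→128→256→512). The deepest features pass
through a bottleneck of 3 convolutional blocks with 2 dense
(concatenation) connections. The decoder performs five ×2 up-samplings;
at each of the four named skip levels the encoder and decoder feature maps
form a length-2 sequence processed by two independent convolutional LSTMs
(forward and reversed order) whose final hidden states are concatenated —
the BConvLSTM fusion. Training minimizes binary cross-entropy (Dice and
BCE+Dice selectable) with Adam; the output is a per-pixel sigmoid
probability, thresholded at 0.5.

**Evaluation.** Pixel confusion counts pooled over the test set;
accuracy, precision, recall, F1, the Dice similarity coefficient
2|E∩Q|/(|E|+|Q|), and ROC/AUC by threshold sweep with trapezoidal
integration.

## Worked example

```r
library(ResBCDUNet)

# a 256x256 phantom with a wall-attached nodule and its exact truth mask
pm <- generatePhantom(PhantomSpec(attachNodule = TRUE, seed = 3))
mask <- extractLungMask(pm$slice)
diceCoef(mask, pm$mask)
#> [1] 0.961408
all(mask[pm$nodule] == 1)   # the closing step recovered the nodule
#> [1] TRUE

# engineered three-channel input and a desk-scale training run
pairs <- lapply(generateCohort(48,
    PhantomSpec(height = 64, width = 64, nVessels = 2, attachNodule = TRUE,
                noduleRadius = 3, seed = 901), jitter = 0.3),
  function(p) list(x = assembleChannels(p$slice), y = p$mask))
model <- buildModel(networkConfig(c(64, 64), baseFilters = 8), seed = 1)
fit <- trainModel(model, pairs[1:40], pairs[41:48],
                  trainConfig(epochs = 30, batchSize = 4,
                              learningRate = 1e-3, seed = 1,
                              earlyStopDice = 0.90))
tail(fit$history, 1)
#>   epoch trainLoss  trainAcc   valLoss    valAcc   valDice
#> 4     4 0.4898518 0.9554321 0.4750781 0.9634094 0.9297855
```

The phantom Dice of ≈ 0.96 reflects the pipeline's 2-px erosion rim; the
training run reaches a held-out Dice above 0.90 within a few epochs because
the phantom classes are separable by construction.

A command-line interface with subcommands `simulate`, `make-masks`,
`preprocess`, `train`, `predict` and `evaluate` is installed under
`inst/cli/resbcdunet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/resbcdunet.R", package="ResBCDUNet"))')" \
  simulate --seed 1 --out sim/
```

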