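Package: ResBCDUNet
Title: Lung CT Segmentation with a ResNet-34/BConvLSTM U-Net and
    Morphology-Based Ground-Truth Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end lung parenchyma segmentation for 2-D CT slices.
    Provides semi-automatic ground-truth mask extraction from
    Hounsfield-unit images (thresholding, border clearing, connected
    components, binary morphology, hole filling), engineering of
    three-channel network inputs (normalized original, Canny edge map,
    dilated binary), a U-shaped segmentation network with a ResNet-34
    encoder, densely connected bottleneck and bidirectional
    convolutional-LSTM skip fusion trained by backpropagation, pixel-level
    evaluation (accuracy, precision, recall, F1, Dice, ROC/AUC), a
    deterministic lung-phantom simulator for testing, and minimal DICOM
    and BMP/PNG raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    png,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
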