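Package: spikelesion
Title: Spiking Neural Networks for Breast Lesion Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for rate-coded spiking neural network (SNN) detection of
    breast lesions in grayscale medical images. Implements leaky
    integrate-and-fire neuron simulation with closed-form membrane and
    interspike-interval solutions, conversion of ReLU layer graphs to spiking
    networks with batch-normalization folding and activation-range
    calibration, a multi-scale saliency-fusion detection network (residual
    backbone, feature pyramid top-down fusion, spatial saliency masking, grid
    detection head), PASCAL-VOC style precision/recall/mAP evaluation, a
    MAC/AC neuromorphic energy model, per-scanner optical-density calibration
    for film mammograms, and a synthetic lesion image generator with VOC-XML
    and YOLO annotation dialects so the whole pipeline runs without external
    datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
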