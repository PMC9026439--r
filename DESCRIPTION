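Package: dbnn
Title: Dual-Branch Convolutional Networks for Longitudinal Ultrasound
    Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early prediction of pathologic complete response to
    neoadjuvant chemotherapy from paired two-timepoint B-mode breast
    ultrasound images. Implements a dual-branch convolutional neural
    network with inter-branch feature sharing (element-wise sum or channel
    concatenation) and weighted late fusion of the two timepoint feature
    vectors, together with the surrounding pipeline: a seeded speckle
    phantom generator for paired synthetic cohorts, frame extraction and
    pairing, ROI cropping, median denoising and standardization,
    class-imbalance augmentation (geometric transforms, Mixup, minority
    upsampling), cross-entropy/Adam training, a full evaluation panel
    (confusion metrics, ROC/AUC, DeLong confidence intervals and paired
    DeLong tests, Mann-Whitney U), and config-driven ablation sweeps over
    depth, sharing mode, fusion weights, augmentation strategy and
    single- versus dual-stage inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    png,
    yaml
Config/testthat/edition: 3
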