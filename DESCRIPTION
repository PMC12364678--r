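Package: PDL1cps
Title: Automated PD-L1 Combined Positive Score Estimation from IHC Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for estimating the PD-L1 Combined
    Positive Score (CPS) on immunohistochemistry images of gastric cancer
    tissue. The pipeline localizes tissue by Otsu thresholding at low
    magnification, tiles it into non-overlapping patches, identifies tumor
    regions by consensus between a patch-level classifier and a pixel-level
    segmenter, detects PD-L1 positive tumor cells, PD-L1 negative tumor cells
    and PD-L1 positive immune cells, and computes the CPS with necrosis
    exclusion, a 0.5 mm immune-cell proximity rule and the CPS >= 1 positivity
    call. Includes a synthetic slide generator with exact ground truth,
    trainable desk-scale models, detection/segmentation/classification
    metrics, Cohen's kappa agreement analysis and a gated-versus-ungated
    efficiency benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    ranger,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'synthetic.R'
    'io.R'
    'preprocess.R'
    'features.R'
    'augment.R'
    'classifier.R'
    'segmenter.R'
    'detector.R'
    'cps.R'
    'oracle.R'
    'evaluation.R'
    'config.R'
    'cli.R'
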