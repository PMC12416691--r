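Package: phantomqa
Title: Automated Quality Assurance Scoring of ACR Mammography Phantom Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for automated quality-control scoring of ACR-style
    mammography accreditation phantom radiographs. Renders synthetic phantom
    images with known per-lesion ground truth (six fibers, five speck groups,
    five masses in a 4x4 grid), standardizes raw or DICOM images through a
    four-stage preprocessing pipeline (photometric normalization, phantom
    localization and alignment, lesion-area cropping, rhombus-windowed
    intensity normalization and grid division), scores the 16 lesions either
    by deterministic guideline rules or by a small trainable dual-output
    (existence/abnormality) classifier with masked focal loss and gradient
    saliency maps, aggregates lesion scores into sequential feature totals
    and a phantom-level pass/fail verdict, and evaluates scorers with
    confusion metrics, ROC/AUC, F1-maximizing thresholds, bootstrap
    confidence intervals and stratified dataset splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
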