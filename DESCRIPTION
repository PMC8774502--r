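Package: shortcutaudit
Title: Auditing and Correcting Shortcut Learning in Skin Lesion Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-agnostic tools to detect, quantify and correct shortcut
    learning in binary skin lesion image classifiers. Dermoscopy archives such
    as ISIC contain elliptical colour-calibration patches that co-occur with
    the benign class only, so a classifier can learn the artefact instead of
    the lesion. The package segments such patches with SLIC superpixels and a
    colour-distance rule, removes them by classical inpainting, composites
    them into artefact-free images, and scores the resulting prediction shifts
    with paired deviation statistics (mean absolute deviation, fraction
    decreased, mean negative deviation, decision-boundary flip rate). It also
    de-biases a training set by replacing artefacts with inpainted tissue and
    retraining, and ships a seeded synthetic dermoscopy generator with ground
    truth masks so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    glmnet,
    grDevices,
    jsonlite,
    Matrix,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
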