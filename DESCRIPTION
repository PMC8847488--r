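Package: embryopcl
Title: Pseudo-Contrastive Labeling for Time-Lapse Embryo Viability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the developmental potential of IVF embryos from time-lapse
    incubator image sequences. Implements a focal-style weighted soft-hinge
    segmentation objective with embryo detection metrics, a time-conditioned
    multi-head frame classifier, first-order ARMA temporal score integration,
    semi-supervised pseudo-contrastive pair labeling with oocyte-age gating,
    the iterated six-stage training cascade (A-F), ROC-based evaluation over
    time and oocyte age, and minimum-error working-point selection. Includes a
    synthetic cohort generator that emulates the statistical structure of
    clinical known-implantation-data (KID) cohorts, so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
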