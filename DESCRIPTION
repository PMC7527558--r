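Package: silicoct
Title: Micro-CT Lung Biomarkers for Preclinical Silicosis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for respiratory-gated in vivo micro-CT
    of mouse lungs in the silica-instillation model of non-resolving
    pulmonary fibrosis. Provides phantom-based Hounsfield unit calibration
    anchored at water = 0 HU and air = -1000 HU, retrospective time-based
    sorting of list-mode projections into respiratory-phase bins,
    threshold-based quantification of mean lung density and
    aerated/non-aerated/total lung volumes over a lung volume of interest,
    and the downstream study statistics (derived lung-function indices,
    Pearson correlations with Sidak adjustment, longitudinal mixed-model
    stage). A synthetic-data module generates calibration phantoms, digital
    thorax volumes across breathing phases, list-mode projection streams
    and longitudinal study cohorts with known ground truth, so every stage
    is testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
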