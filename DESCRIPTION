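Package: cortexstage
Title: Cortical Signatures and Disease-Stage Classification for
    Surface-Based Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives data-driven cortical signatures from vertex-wise
    cortical thickness comparisons on triangulated surface meshes and
    evaluates them, together with intracranial-volume-corrected
    subcortical volumes, as disease-stage classifiers for Alzheimer's
    disease in Down syndrome. Provides icosphere surface geometry,
    iterative FWHM-calibrated smoothing, vertex-wise covariate-adjusted
    group models with permutation-based cluster correction, ROC/AUC
    staging analyses, Dice overlap and spatial correlation of effect-size
    maps, a synthetic cohort generator emulating the demographic and
    spatial effect structure of a Down-syndrome Alzheimer cohort, and
    readers/writers for FreeSurfer curv, label and binary surface files
    and GIFTI surface/functional files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
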