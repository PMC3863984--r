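Package: hearclass
Title: Two-Layer Structural and Functional MRI Classification of Infant
    Hearing Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies hearing-impaired (HI) from normal-hearing (NH)
    infants using spatially normalized structural MR volumes and
    functional contrast maps. Structural volumes are partitioned into
    cubes and sliced along three orientations; 2D SIFT keypoints are
    scored by a similar-feature-set likelihood ratio and classified per
    cube by linear support vector machines, yielding a per-subject Csum
    score. Functional contrast maps are vectorized with a bag-of-words
    dictionary of top-5 percent connected regions of interest, merged by
    average-linkage hierarchical clustering, filtered by
    correlation-based feature selection, and scored by a linear SVM. A
    second-layer linear SVM fuses the two scores. Includes a synthetic
    cohort generator, leave-one-out cross-validation with equal-error-rate
    thresholds, ROC/AUC summaries, and a feature-selection stability
    index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    e1071,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
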