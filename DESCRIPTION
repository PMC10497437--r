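Package: cordT2
Title: Automated Spinal Cord T2 Signal-Intensity Quantification for
    Degenerative Cervical Myelopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Slice-wise quantification of T2 signal intensity (T2-SI) over a
    segmented cervical spinal cord: per-slice cross-sectional area and mean
    signal curves, subdivision into cervical disc levels (C2/3 to C6/7) by
    vertebral body centers, per-level mean/SD/range statistics and the scale
    invariant T2 myelopathy index (T2-MI = range x 100 / mean). Includes a
    seeded synthetic phantom generator with ground-truth cord masks, focal
    hyperintense lesions and Rician noise; a classical intensity-based
    phantom segmenter; inter-rater agreement statistics (majority consensus,
    percent agreement, Fleiss' kappa); age- and level-matched control
    construction; Mann-Whitney U and exact binomial comparisons; and ROC
    analysis with Youden and closest-to-top-left cutoff derivation. A cohort
    pipeline orchestrates the full analysis on synthetic cohorts or on
    NIfTI volumes with externally supplied cord segmentations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
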