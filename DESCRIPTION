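Package: modscreen
Title: Ordinal Modifier-Screen Statistics and Polytene Immunofluorescence
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for RNAi genetic modifier screens that score an
    ordinal wing-defect phenotype, and for batch quantification of
    immunofluorescence signal on polytene chromosome spreads. Implements the
    Mann-Whitney rank-sum test with tie-corrected normal approximation and an
    exact enumeration mode, blister-wing exclusion, enhancer/suppressor
    classification, and screen report generation; chromosome-mask
    segmentation, antibody/DAPI ratio quantification, replicate group
    comparison, and a two-channel colocalization statistic. Ships synthetic
    generators for ordinal wing-score datasets (proportional-odds shift
    model) and banded chromosome-spread image batches with ground truth, so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
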