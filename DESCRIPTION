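Package: tilax
Title: Activation and Exhaustion Analysis of Tumour-Infiltrating Lymphocytes
    in Multiplexed Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell analysis of tumour-infiltrating lymphocytes (TILs)
    from quantified multiplexed-immunofluorescence tissue images. Provides
    marker quality control and trimmed z-score normalisation, a PCA-derived
    activation gradient that scores each CD8+ cell on a continuum from
    activation (CD69/OX40) to exhaustion (TIM3/LAG3), Active/Transition/
    Exhausted classification of tissue cores and patients with FDR control
    and resampling robustness curves, consensus cell phenotyping from three
    clustering algorithms with a rule-based annotator, permutation-based
    spatial neighbourhood analysis with cross-image integration, cohort-level
    statistics against histopathology, and correlation-based assignment of
    single-cell RNA profiles to immune signatures for external validation.
    A synthetic-cohort generator with planted ground truth supports testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
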