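Package: mzldt
Title: Direct-Infusion Metabolomics Pipeline for Pathway-Based Diagnostic Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A laboratory-developed-test style pipeline for direct-infusion
    high-resolution mass spectrometry metabolomics. Takes per-sample peak
    lists through internal-standard intensity recalibration, cross-sample m/z
    alignment, positive-mode adduct search against a metabolite table,
    biochemical-context-driven putative annotation, permutation-based pathway
    overrepresentation scoring, per-subject Z-score metabolite selection with
    leave-one-out controls, a panel-based diagnostic score with threshold
    classification, and a pathway-names-cloud visualization. Includes a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
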