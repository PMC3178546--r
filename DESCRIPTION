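Package: getem
Title: Gene Expression Templates for Tissue Classification
Version: 0.1.0
Authors@R:
    person("GET", "Maintainers", email = "getem@example.org", role = c("aut", "cre"))
Description: Derives compact tissue-classifying gene signatures from multiple
    expression compendia by coefficient-of-variation ranking, cross-dataset
    intersection and correlation-clustering redundancy removal; builds
    per-tissue gene expression templates (GETs); and predicts the tissue or
    physiological state of new samples by maximal Pearson or Spearman
    correlation to the templates (1-nearest-neighbour over templates).
    Includes developmental-trajectory regression, cancer-deviation scoring,
    evaluation reports, a synthetic compendium generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
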