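Package: fuzzpat
Title: Unsupervised Fuzzy Pattern Discovery in Mixed-Mode Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free discovery of statistically significant association
    patterns in mixed-mode (continuous and categorical) gene expression
    tables. Attributes are clustered by the normalized interdependence
    redundancy measure (mutual information over joint entropy) using a
    k-modes algorithm with model selection over the number of clusters;
    crisp attribute clusters are then fuzzified into per-attribute degrees
    of membership so that patterns spanning cluster boundaries remain
    discoverable. Continuous attributes are discretized against each
    cluster's representative attribute (its mode) by maximizing
    interdependence, high-order event associations are screened by adjusted
    residuals, and class-conditioned patterns yield weight-of-evidence
    classification rules for post-hoc evaluation. Includes a reproducible
    generator for a benchmark mixed-mode dataset with planted cluster
    structure and tuple-replacement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
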