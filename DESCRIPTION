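Package: svhotspots
Title: Somatic Structural Variant Hotspots, Complex Events and Copy-Number States
Version: 0.1.0
Authors@R: person("GEL", "CRC Analysis", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of somatic structural variant (SV) hotspots in cancer
    whole-genome cohorts by covariate-aware negative binomial background
    modelling, length- and count-preserving SV permutation, piecewise constant
    fitting of inter-mutational distances and empirical false discovery rates;
    classification of rearrangement clusters as chromothripsis or chromoplexy;
    permutation-based complex-SV enrichment; and an allele-specific copy-number
    layer (whole-genome duplication calls, six-category CNA states, normalized
    SegCN preparation, purity/ploidy re-estimation and arm-level events).
    Includes a synthetic-cohort generator so every stage is testable without
    access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    MASS,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
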