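Package: intePath
Title: Integrative Pathway Prioritization from Proteomic and
    Phosphoproteomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pathway prioritization for paired protein-abundance and
    phosphosite-abundance studies of tumor versus normal tissue.
    Provides minimum-value imputation and phosphosite-to-gene collapse,
    two-sample differential-abundance testing with Benjamini-Hochberg
    control, integration of the two omic layers (intersection, union,
    single-layer and full summed-fold-change profiles), three pathway
    scoring engines (hypergeometric over-representation, weighted
    Kolmogorov-Smirnov running-sum enrichment with a permutation null,
    and topology-based perturbation propagation with combined evidence
    p-values), and a target-pathway rank-evaluation harness with
    normalized ranks, top-K overlaps and subtype comparisons. A
    synthetic-data generator with planted, topology-aware pathway signal
    makes the whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Proteomics, Pathways, GeneSetEnrichment, NetworkEnrichment
RoxygenNote: 7.3.3
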