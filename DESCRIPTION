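Package: mcRules
Title: Monte Carlo Feature Selection and Rule-Based Classification of
    Microbial Annotation Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretable multi-class classification of microbial strains
    from functional-annotation count profiles (ARDB/CARD/KEGG/VFDB-style
    feature tables). Implements Monte Carlo feature selection: relative
    importance scores aggregated over ensembles of information-gain decision
    trees grown on random feature projections; incremental feature selection
    under stratified cross-validation scored by the multi-class Matthews
    correlation coefficient; RIPPER-family ordered rule-list induction with
    reduced-error pruning and description-length stopping; an empirical
    random-subset significance test for the selected features; and a
    synthetic-table generator with planted rule-based class structure for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
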