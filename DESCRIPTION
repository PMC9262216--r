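Package: ccea
Title: Conjunctive Clause Evolutionary Algorithm for Feature Selection in
    Small Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers parsimonious conjunctive clauses -- logical ANDs of
    feature-interval conditions -- that distinguish a target class (for
    example, children with autism spectrum disorder) from controls in a
    subjects-by-features table mixing behavioral scores with
    FreeSurfer-style regional brain measures. Clauses are scored by the
    hypergeometric probability mass function and pruned by per-feature
    sensitivity, so that feature interactions can be detected even in the
    absence of main effects. Selected feature sets are validated with
    k-nearest-neighbors leave-one-out cross-validation and train/test
    classification. A synthetic-cohort generator with planted conjunctive
    rules makes every stage testable without access to the original study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, StatisticalMethod
RoxygenNote: 7.3.3
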