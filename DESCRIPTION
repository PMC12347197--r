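Package: gnrSelect
Title: Genetic-Embedded Nuclear Reaction Optimization for Gene Selection
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper gene selection for microarray and other expression
    matrices. Combines a univariate relevance filter (two-class F-score or
    one-way ANOVA F) with a physics-inspired population metaheuristic in
    which a nuclear "fusion" refinement step is probabilistically replaced
    by a genetic uniform crossover with the best-known solution. Candidate
    gene subsets are scored by a linear support vector machine under
    leave-one-out cross-validation. Includes preprocessing (mean
    imputation, per-gene Z-score normalization, label encoding), ARFF/CSV
    input, a synthetic-data generator with planted discriminative genes,
    and a multi-run experiment harness reporting best/average/worst
    accuracy with confidence intervals across subset sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    foreign,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
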