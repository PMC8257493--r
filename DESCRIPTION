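Package: deepheno
Title: Ontology-Based Deep Phenotyping of Cohorts with Positive and
    Negative Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of cohorts annotated with
    Human Phenotype Ontology (HPO) terms, including explicitly asserted
    absent ("negative") phenotypes. Provides OBO parsing into a directed
    acyclic graph, upward propagation of positive annotations and
    downward propagation with lossless pruning of negative annotations,
    term frequency and information-content tables, exact genotype-
    phenotype association testing with false-discovery-rate control,
    Resnik-style phenotypic similarity with permutation null
    distributions, logistic principal component analysis of binary
    phenotype matrices with classifier-based evaluation for variant
    function (gain- versus loss-of-function) prediction, protein-level
    variant parsing with ion-channel topology mapping, and a seeded
    synthetic-cohort generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
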