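Package: yeastenv
Title: Ontology-Driven Analysis of Yeast Isolation Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An ontology engine for budding-yeast isolation environments
    (single-parent class hierarchies, relational and modifier properties,
    strain instances, transitive-closure membership queries, OWL RDF/XML and
    TSV serialization) together with a genotype-to-ecology association
    pipeline: balanced consensus random forests on KEGG-ortholog
    presence/absence features with permutation importance, cross-model
    consensus feature selection, per-ortholog Fisher exact tests, and
    Benjamini-Hochberg-corrected pathway over-representation. Includes a
    synthetic-data generator with planted gene-environment effects so the
    whole pipeline can be exercised and validated without external data.
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
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
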