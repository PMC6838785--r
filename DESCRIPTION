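Package: panneo
Title: Pan-Allele HLA-Peptide Binding, Immunogenicity and Neoantigen
    Prioritization with Recurrent Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts HLA class I peptide presentation and immunogenicity
    with a stacked bidirectional GRU classifier with attention, trained on
    one-hot encoded peptide/HLA pseudo-sequence pairs. Implements IEDB-style
    record curation with pseudo-pair class balancing, a dual-model
    (binding + immunogenicity) neoantigen scanning pipeline with a
    mutation-level presentation score and top-k ranking, position frequency
    matrix motif extraction, evaluation metrics with 5-fold
    cross-validation, and a seeded synthetic-data generator with planted
    binding rules for end-to-end testing.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
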