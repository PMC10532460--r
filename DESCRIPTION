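Package: sprpep
Title: Structure-Property Models for Drug-Resistance of Amino Acid Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a missense amino-acid substitution in a drug-target
    protein confers drug resistance, from sequence alone. Substitution-centered
    peptide windows are converted to explicit-hydrogen molecular graphs, described
    by recursive Multilevel Neighborhoods of Atoms (MNA) substructure descriptors,
    and classified by a naive-Bayes-like scorer with empirical Pa/Pi calibration
    from leave-one-out scores. Includes MOL V2000/V3000 SD file input/output with
    annotation tags, leave-one-out and stratified k-fold AUC estimation, a peptide
    length by descriptor level grid search, threshold scans, and a seeded synthetic
    data generator with a plantable sequence-context signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
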