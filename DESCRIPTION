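Package: smorfselect
Title: Detecting Selection on Small ORFs Encoded in Bacterial Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how many short open reading frames (10-50 amino
    acids) inside annotated bacterial small RNAs are under selection to
    encode proteins. Each candidate ORF is scored with three sequence
    features (Shine-Dalgarno hybridization free energy against the
    anti-SD tail of the 16S rRNA, a dN/dS likelihood-ratio statistic from
    a codon substitution model, and a phase-specific Z-curve composition
    score), the features are combined with a cost-sensitive bagged
    decision-tree classifier, and the excess of high-scoring ORFs over a
    matched mock-ORF null is estimated with an empirical false discovery
    rate procedure. Auxiliary evidence modules call translation from
    strand-specific ribosome-profiling coverage and classify candidate
    peptides as type I toxin-like. A synthetic-data generator produces
    genomes with planted coding ORFs, ortholog codon alignments evolved
    under a chosen dN/dS, and coverage tracks for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    methods,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    rpart,
    rtracklayer,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
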