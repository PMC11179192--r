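Package: splicescreen
Title: Triage and Penalized-Logistic Scoring of Intronic Splice-Region Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens human intronic single-nucleotide variants for splicing
    errors. Variants from VCF are triaged into donor (5'ss) and acceptor
    (3'ss) windows around annotated introns, split by whether they create a
    novel AG dinucleotide, and scored with route-specific LASSO-penalized
    logistic models built on interpretable features: evolutionary
    conservation, U2 snRNA pairing energy against the branch region, local
    RNA folding energy and structural openness, polypyrimidine-tract
    content, splice-site position-weight-matrix strength and distance to the
    splice site. Includes model training with cross-validated penalty
    selection and Youden-J cutoff choice, evaluation metrics, a synthetic
    massively-parallel splicing-assay generator labeled by Fisher's exact
    test, and a branchpoint query store.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Biostrings,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
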