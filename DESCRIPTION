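Package: peplm
Title: Chemical Language Modeling Toolkit for Modified and Cyclic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates chemically modified peptide SMILES (unnatural residues,
    D-stereocenters, five cyclization chemistries, backbone N-methylation,
    PEGylation), trains an n-gram SMILES tokenizer with atom-aware
    pretokenization, pretrains a rotary-position-embedding BERT-style encoder
    with the masked-language-model objective, and evaluates membrane
    permeability regression under embedding-based leave-one-cluster-out
    splits with k-fold ensemble finetuning. All stages run at desk scale on
    synthetic fixtures with planted structure-permeability relations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
SystemRequirements: python (>= 3.8) with rdkit, on PATH
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
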