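Package: activemir
Title: Active miRNA Inference from Gene Expression and miRNA-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies functionally active microRNAs in cancer from tumour
    versus normal gene expression and a miRNA-to-gene interaction network,
    without using miRNA expression for inference. Per-patient normalized
    differential expression is regressed on a signed miRNA target-indicator
    matrix with an elastic-net penalty (coordinate descent, cross-validated
    penalty strength averaged across the cohort); miRNAs with a consistent
    signed influence across most patients are called active, optionally
    validated against observed miRNA differential expression with a
    permutation test on sign concordance. Includes a synthetic-cohort
    simulator with planted active miRNAs and four noise models (spurious and
    missing network edges, gene-gene diffusion, expression-level noise) for
    robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
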