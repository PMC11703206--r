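Package: pepbound
Title: Free-Energy Regression for Peptide-Display Affinity Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers additive binding free-energy matrices (delta-delta-G/RT)
    for peptide-recognition domains from multi-round peptide-display
    selection experiments sequenced before and after binding. Paired
    input/bound read counts are modelled with a binomial likelihood over a
    two-mode enrichment model (sequence-specific binding plus non-specific
    background), fitted by quasi-Newton optimisation with analytic
    gradients. Fitted models score phosphosites, rank candidate interaction
    partners, and predict the effect of missense variants on binding.
    Includes processing of merged amplicon reads into count tables, a
    log-enrichment matrix baseline, and a synthetic multi-round selection
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
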