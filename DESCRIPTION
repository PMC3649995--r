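Package: mtqtl
Title: Joint Mapping of cis-eQTLs Across Multiple Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian framework for mapping expression quantitative trait
    loci (eQTLs) jointly across multiple tissues or conditions.  Computes
    configuration-specific Bayes factors under a two-level normal prior on
    standardized effects (with optional intra-individual residual
    correlation), combines them by Bayesian model averaging into SNP- and
    gene-level test statistics, fits a hierarchical model across genes by
    expectation-maximization to estimate the null fraction and the
    frequencies of eQTL-sharing configurations, and assesses significance
    with gene-level permutation p-values and Storey q-values.  Includes
    tissue-by-tissue and ANOVA baselines, pairwise pi1 sharing estimates,
    and a synthetic-data generator for power and sharing-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
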