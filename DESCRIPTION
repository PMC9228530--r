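Package: dysbiome
Title: Compositional Diversity, Differential Abundance and Dysbiosis
    Analysis for Two-Group 16S Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feature-table-to-findings pipeline for two-group 16S rRNA
    gut microbiome studies (e.g. patients versus healthy controls):
    contaminant and ultra-rare taxon filtering, rarefaction, alpha and
    beta diversity with Kruskal-Wallis and PERMANOVA group tests and
    principal coordinates ordination, compositional differential
    abundance (ANCOM W statistic plus CLR-lasso, coda-lasso and selbal
    balance selection with a cross-method consensus), ALDEx2-style CLR
    effect sizes for pathway count tables, and three dysbiosis
    statistics over a healthy reference set (median Bray-Curtis
    quantile test, dissimilarity-overlap curve analysis, and the CLOUD
    nearest-neighbour outlier test). A Dirichlet-multinomial cohort
    simulator with planted differential taxa and planted dysbiotic
    outliers makes every stage verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
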