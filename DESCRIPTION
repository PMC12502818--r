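Package: microfam
Title: Family-Based Microbiome Cohort Analysis for IBD Dysbiosis Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for family-based 16S amplicon cohort
    studies of inflammatory bowel disease. Provides a synthetic
    family-cohort generator (pedigrees, negative-binomial count tables,
    biomarkers coupled to a latent dysbiosis score, heritable taxa);
    normalisation, centred log-ratio transformation and prevalence
    filtering; alpha diversity, Bray-Curtis/Jaccard dissimilarity,
    ordination, conditioned PERMANOVA and multivariate dispersion tests;
    negative-binomial Wald differential abundance with covariates; a
    modified microbial dysbiosis (MD) index with segmented
    dysbiosis-diversity model selection; covariate-adjusted linear models
    and partial correlations combined across methods via Brown's method;
    Dirichlet-multinomial mixture community clustering with Laplace model
    selection; co-abundance network inference with permutation null models,
    graphlet profiles and between-network distances; and pedigree-kinship
    REML heritability of taxon abundances.
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
    readr,
    ggplot2,
    generics,
    MASS,
    vegan,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    emmeans,
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
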