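Package: gwaspect
Title: Seed Aspect-Ratio GWAS with Kinship Mixed Models, Linkage
    Disequilibrium and Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for genome-wide association analysis of
    seed shape in diversity panels of inbreeding crops such as peanut.
    Measures seed aspect ratio from binary seed images by equivalent-ellipse
    moments, applies per-marker quality control (missingness, heterozygosity,
    minor allele frequency), summarises population structure by principal
    coordinate analysis of allele-sharing distances, fits a kinship mixed
    linear model per marker with Benjamini-Hochberg false discovery rate
    control, estimates pairwise linkage disequilibrium (D' and r-squared)
    from unphased genotypes by a two-locus EM algorithm with decay-curve
    fitting and candidate-window extraction, and ranks markers by bootstrap
    stability selection under an elastic-net penalty with theoretical and
    permutation-based false-discovery thresholds. A synthetic-data module
    simulates structured genotype panels, phenotypes and seed images so the
    whole pipeline is testable without array data.
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
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
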