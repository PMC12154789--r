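Package: cdhscan
Title: Detection of Chromosomal Drive Haplotypes from Genotyping-by-Sequencing Tag Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores large chromosomal drive haplotypes (the maize Ab10 and
    K10L2 chromosome-10 variants and the supernumerary B chromosome) in
    low-coverage genotyping-by-sequencing data. Computes a binned tag index
    from tag counts, calls presence/absence by control-anchored iterative
    k-means clustering with consensus over repeated rounds, estimates pseudo
    copy number by normalisation to single-copy core genes, types Ab10
    haplotypes with a random forest, and provides the downstream association
    toolkit: principal-component-adjusted GWAS, stepwise GLM simplification
    and deviance partitioning across variable classes. Includes a synthetic
    data generator emulating the tag-count, manifest, genotype and
    environment inputs so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
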