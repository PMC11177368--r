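Package: qtlfine
Title: Mixed-Model GWAS, Variance Partitioning and ROH-Based Fine-Mapping
    of Quantitative Trait Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quantitative-genetics toolkit for SNP-based analysis of
    continuous and ordinal conformation traits: genomic relationship
    matrices (whole-genome, per-chromosome, leave-one-chromosome-out and
    QTL-window partitions with exclusion buffers), average-information REML
    for one or many genomic variance components with likelihood-ratio
    testing, bivariate REML for global and region-local genetic
    correlations, mixed-linear-model association scans with
    leave-one-chromosome-out polygenic control and conditional analyses,
    BLUP prediction of component-specific breeding values,
    runs-of-homozygosity detection with scanning-window rules and
    cross-individual shared-segment analysis, minimal variant-consequence
    annotation on a toy gene model, and a two-pronged (linkage
    disequilibrium and identity-by-descent sharing) causal-variant
    fine-mapping procedure. Includes a founder-mosaic simulator that plants
    a major additive QTL in linkage-disequilibrium-structured genotypes so
    that every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
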