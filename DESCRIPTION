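Package: triokf
Title: Knockoff-Based Fine Mapping for Parent-Offspring Trio Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for family-based fine mapping of
    disease-associated variants with knockoff genotypes. Generates phased
    parent-offspring trio cohorts with blockwise linkage disequilibrium and
    affected-proband ascertainment; reads and writes phased VCF and PED
    pedigrees with Mendelian-error, Hardy-Weinberg and allele-frequency
    quality control; partitions variants into LD blocks; constructs trio-aware
    knockoff genotypes by within-block residual permutation of parental
    haplotypes with offspring knockoffs derived from the inferred transmission
    pattern; scans the region with overlapping windows at multiple resolutions
    using a LASSO-weighted burden family-based association test against the
    knockoffs with false discovery rate control; estimates per-variant odds
    ratios by case/pseudo-control conditional logistic regression; and
    computes analytic and simulated power of the transmission disequilibrium
    test over a minor-allele-frequency by odds-ratio grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
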