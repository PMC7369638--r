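Package: svstrat
Title: Population Stratification, Introgression and Expansion Analysis of
    Structural-Variant Callsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of structural-variant (SV) genotypes across
    many populations: quality control of cell-line derived cohorts (coverage
    aneuploidy screening, region masking, exact heterozygote-excess batch
    filtering), callset engineering (fragment merging, reciprocal-overlap
    matching, novelty and allele-frequency concordance), population
    stratification scans (maximum allele-frequency difference against Hudson
    Fst, Vst with label-permutation tests, the population branch statistic
    against an SNV null), private-variant discovery, archaic-introgression
    candidate filtering, and detection of regionally restricted runaway
    copy-number expansions. Includes a seeded synthetic-cohort generator
    (Balding-Nichols structured frequencies, multiallelic copy-number ladders,
    archaic sharing, batch artifacts, aneuploid coverage) with ground-truth
    labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
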