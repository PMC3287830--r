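Package: rareload
Title: Rare-Variant Mutational Load Association Testing Under Missing
    Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene-based association testing of rare genetic variants by
    their mutational load: for each gene, the proportion of successfully
    genotyped rare variants at which an individual carries at least one
    minor allele enters a generalized linear model, individuals are
    weighted by their genotype call counts to accommodate differential
    call rates, and association is assessed by a likelihood-ratio test.
    Includes per-ancestry-stratum analysis combined by inverse-variance
    fixed-effects meta-analysis, two missing-genotype injection models
    (uniform random and allele-specific failure rates), a synthetic
    exome-like data generator with Balding-Nichols population structure
    and known causal architecture, and a replicate simulation harness
    estimating power and type I error at Bonferroni-corrected
    significance thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor,
    optparse,
    yaml,
    ggplot2
Config/testthat/edition: 3
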