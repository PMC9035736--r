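Package: crossorigin
Title: Ancestral Origin Attribution of Variant Sites in Composite Breeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes variant sites expressed in a composite (crossbred)
    cohort to their maternal or paternal ancestor breed. Reads per-sample
    genotypes for two ancestor cohorts and one offspring cohort from VCF,
    applies GATK-style hard filters, an SNP-cluster filter and VCFtools-style
    cohort filters, calls cohort major genotypes under strict proportion
    thresholds, detects ancestor-informative sites (homozygous, mutually
    inconsistent major genotypes), assigns each screened offspring site to an
    ancestor of origin, and aggregates assignments to genes through a
    1,000-bp window rule. Ships a two-population admixture simulator that
    emits VCF, GFF3 and a per-locus truth table so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
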