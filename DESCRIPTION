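Package: wgaQC
Title: Detection of Whole-Genome-Amplification Artifacts in Germline
    Variant Calls
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing and detecting technical artifacts
    introduced by whole genome amplification (WGA, in particular multiple
    displacement amplification) in cohort-scale germline variant calls.
    Provides a synthetic diploid exome cohort simulator with a truth
    ledger of injected artifact classes (homopolymer slippage indels,
    chimeric large insertions copied from proximal reference sequence,
    and gene-level coverage dropout), an indel context taxonomy
    (homopolymer+, large, other), one-sided Fisher exact enrichment of
    indel alleles in amplified samples, a local copy-origin search for
    large indels, replicate genotype discordance, loss-of-function
    burden construction with Type II ANOVA variance decomposition, and
    one-vs-rest logistic burden association with Bonferroni control and
    inflation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    boot,
    car,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
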