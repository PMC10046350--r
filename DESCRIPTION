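Package: ampdep
Title: Collateral Dependency Screening for Cancer Genomic Amplifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates gene-level copy-number profiles with CRISPR
    knockout gene-effect scores to identify collateral gene dependencies
    generated by high-copy genomic amplifications. Provides ploidy-aware
    amplification calling from relative copy numbers, coamplicon
    construction by copy-number correlation, genome-wide differential
    dependency screens with FDR control, positional gene-set overlap
    analysis and preranked gene set enrichment analysis, Kaplan-Meier and
    log-rank survival comparisons for amplified tumors, druggability-based
    target prioritization, and assessment of mRNA expression as a
    dependency biomarker. A synthetic-data generator with a ground-truth
    manifest supports parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
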