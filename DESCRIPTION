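Package: cnvrscan
Title: Copy Number Variation Region Scanning and Dosage-Effect Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variation regions (CNVRs) from windowed
    read-depth matrices, classifies them as loss, gain or mixed ("both")
    regions, and links them to a behavioral phenotype through a composite
    aggressive score, the V_ST population-differentiation statistic, a
    kinship-corrected mixed linear model association scan, cis/trans dosage
    eQTL against gene expression, and qPCR 2^(-dCt) relative copy number
    validation with ROC marker evaluation. Ships a synthetic cohort
    generator that emulates a two-group extreme-phenotype design with a
    causal dosage-effect CNVR, so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
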