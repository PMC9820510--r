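Package: ctdnaflow
Title: Ultrasensitive Circulating Tumor DNA Detection with UMI Consensus
    Error Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for detecting circulating tumor DNA (ctDNA)
    in ultra-deep targeted plasma sequencing. Implements unique molecular
    identifier (UMI) family grouping and molecular consensus calling with
    base-quality aware voting, mate-overlap clipping, panel-restricted pileup
    and frequency-based candidate calling, tumor-informed and tumor-naive
    stringent variant filtration against COSMIC/TCGA-style annotation flags,
    a Fisher exact "rescue" test of caller-missed tumor variants against
    pooled control plasmas, and cohort-level diagnostic metrics (sensitivity,
    specificity, positive predictive value) with exact Clopper-Pearson
    confidence intervals and clinicopathological association screens. A
    seeded synthetic read generator with a known truth table exercises the
    pipeline down to variant allele frequencies of 0.03 percent (3 mutant
    molecules among 10,000 wild-type).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
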