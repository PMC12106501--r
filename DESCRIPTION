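Package: delscreen
Title: Intensity-Based Screening for Single-Exon Deletions in SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rare heterozygous single-exon deletions (such as the
    Finnish founder MLH1 exon 16 deletion) from SNP-array probe-set
    intensity data at biobank scale. Allele intensities are summed to
    locus-level totals, quantile-normalized per locus to the standard
    normal across samples, reduced to two robust per-sample features
    (deletion-vs-flank median difference and a piecewise median absolute
    deviation), and classified by explicit thresholds into carrier,
    negative, and ambiguous calls. Includes a synthetic-cohort simulator
    so the whole pipeline is testable without access to restricted
    biobank data, plus evaluation utilities (confusion counts, positive
    predictive value, prevalence reporting) and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
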