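Package: chipfold
Title: Fold-Change ChIP-Seq Peak Calling and Nutrient-Stress Occupancy
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested pipeline for histone-modification
    occupancy analysis between two growth conditions: ChIP-seq peak
    calling by sustained IP/input fold change with proximity merging,
    differential occupancy over consensus peaks, closest-TSS gene
    assignment with polymerase/biotype filtering, hypergeometric gene-set
    enrichment with fold-enrichment scoring, TSS-anchored and
    transcript-scaled metagene profiles with mean smoothing and linear
    length interpolation, RPKM expression quantiles, a conditional
    binomial differential-expression test, and condition-versus-mutant
    dependence scatters. Ships a synthetic-data generator with planted
    truth (enriched intervals, differential genes, an enriched term) so
    every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rtracklayer,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
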