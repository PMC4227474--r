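Package: respmode
Title: Response-Mode Analysis of Trinary Transcriptome Call Tables
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gene-by-contrast tables of trinary
    expression response calls (up / unchanged / down), as produced by
    differential-expression pipelines. Cross-tabulates response modes over
    one or more treatment contrasts with independence-expected counts,
    observed/expected enrichment ratios and a chi-squared statistic;
    classifies hormone-responsive genes into mechanistic clusters by
    rule-based call-pattern predicates and reconciles two inhibitor
    analyses into stringent and loose clusters; computes
    background-normalised functional-category enrichment with bootstrap
    means and standard deviations; performs exhaustive 4-10 bp promoter
    motif over-representation scans (chi-squared, both strands) with
    IUPAC cis-element catalog matching and promoter extraction; ranks
    expression-change experiment panels against a top-n signature by a
    Euclidean-distance-derived relative similarity score; and generates
    fully synthetic inputs with planted structure so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Biostrings,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
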