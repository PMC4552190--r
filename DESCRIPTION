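Package: rankwin
Title: Rank-Ordered Sliding-Window Pathway Enrichment for Annotated
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway-based analysis of annotated de novo transcriptomes,
    built around a sliding-window binomial enrichment statistic: ESTs are
    ranked by expression level or by between-condition ratio, and subsets
    of GO/KEGG-annotated ESTs over-represented in windows of consecutive
    ranks are flagged with Bonferroni family-wise error control. Includes
    FPKM normalisation from read counts, fold-change based
    differential-expression flagging, enzyme-level (EC-grouped) summative
    expression panels with a hypergeometric panel-overlap test,
    batch-culture physiology calculators (exponential growth rate from
    cell-dry-weight series, chlorophyll content, PSII quantum yield, lipid
    content as percent of dry weight), and a seedable synthetic-data
    generator that plants rank-coherent term subsets with known ground
    truth for validating the detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
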