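Package: paslab
Title: Pathway Activation Scoring and Correlation Screens for Tumor
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores molecular pathway activation from case-to-normal
    expression ratios with signed activator/repressor gene roles, and
    provides the surrounding analysis chain used in knockdown and
    pan-cancer transcriptomic studies: probe aggregation and quantile
    normalization, per-cohort expression-distribution clustering with a
    high-expressor-fraction statistic, immune-signature and
    pathway-association correlation screens under two-stage false
    discovery rate control, and drug-sensitivity versus gene-dependency
    correlation across cell-line panels. Includes seeded synthetic-data
    generators with planted effects so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
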