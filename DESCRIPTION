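Package: vtrial
Title: Design, Quality Control and Analysis of Crop Variety Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for multi-environment crop variety trials:
    standardized trait definitions with an entity-attribute-value record
    store, automated grouping and randomized complete block layout
    generation with check (CK) varieties, a rules-based data quality
    control engine (range, enumeration, format, consistency and
    statistical checks), trial precision and variety-difference statistics
    (coefficient of variation, two-way ANOVA with interaction, LSD
    multiple comparisons, relative LSD, genetic coefficient of variation,
    CK comparisons), rule-based promotion decisions, entropy-weighted
    TOPSIS comprehensive ranking, GGE (genotype main effect plus
    genotype-by-environment interaction) biplot analysis, a synthetic
    trial simulator with configurable variance components and abnormal
    value injection, and one-command Markdown trial reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
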