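Package: micromediate
Title: Exposome-Gut Microbiome-Health Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for quantifying how much of an environmental
    or lifestyle exposure's association with a health outcome is transmitted
    through the gut microbiome. Derives coded exposure variables from
    questionnaire responses, environmental time series, and mycotoxin source
    tables; computes ten gut-microbiome mediator indices (alpha diversity,
    Bray-Curtis principal coordinates, phylum and Gram-stain ratios, and
    functional-guild abundances) from a genus-level count table; screens
    exposure-mediator and exposure-outcome associations with
    heteroskedasticity-consistent bivariate regression under a dual
    FDR/effect-size criterion; and estimates direct and microbiome-mediated
    indirect effects with bootstrap and distribution-of-product confidence
    intervals, classifying each pathway as full, partial, or inconsistent
    mediation. Includes a synthetic-cohort generator with planted effects
    for parameter-recovery validation, and a Kolmogorov-Smirnov-gated
    subsampler for standardizing unevenly sampled environmental microbiome
    collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    sandwich,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
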