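Package: vulnstrat
Title: Vulnerability-Based Spatial Sampling Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing spatial sampling strata from unit-level
    vulnerability indicators. Builds hazard-exposure and adaptive-capacity
    composite indices from raw indicator fields (range standardization to a
    common 0-10 scale, polarity orientation, population-weighted aggregation,
    weighted linear combination), classifies them with Fisher-Jenks natural
    breaks into an ordered [H,A] vulnerability rating, and aggregates
    contiguous spatial units into strata with comparable measures of size
    (expected births per year) and optimal within-stratum homogeneity, subject
    to probability-sampling rules (full coverage, contiguity, bounded stratum
    count, measure-of-size tolerance). Includes a compliance validator,
    homogeneity diagnostics, recruitment arithmetic, a synthetic-county
    generator for testing, and a packaged fixture transcribed from a published
    county stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
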