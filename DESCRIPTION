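Package: enforcelens
Title: Enforcement Indicators and Spatial Targeting Analysis for Amazon
    Deforestation Policy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct environmental law-enforcement indicator
    series for the Brazilian Amazon and to measure how well enforcement
    targets deforestation. Implements ingestion and filtering of
    infraction-notice, embargo and confiscation records into annual
    indicators; a kernel-heatmap spatial-match statistic (quartic or
    Gaussian kernel densities of fines and deforestation, lowest-quartile
    masking, masked pixel-wise Pearson correlation with a 4-year moving
    average); a Forest Code balance and potentially-illegal-deforestation
    classifier with riparian preservation (APP) buffers, legal-reserve
    deficits, minimum mapping unit filtering and notice-to-holding
    attribution; operational-efficiency metrics (deflated, currency
    converted expenditure per sanction); and a fully synthetic landscape
    generator with known ground truth that emulates the statistical
    structure of cadastre, deforestation and enforcement data so the whole
    pipeline can be exercised and validated without access to the national
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
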