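Package: mchequity
Title: Socioeconomic Inequity Measurement for Maternal and Child Health Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring socioeconomic-related inequity in binary
    maternal-and-child-health indicators from household survey microdata.
    Builds an asset-based household wealth index by principal component
    scoring, ranks households into weighted quintiles and deciles, computes
    concentration curves and concentration indices (curve, discrete and
    covariance forms) with analytic or bootstrap standard errors, and
    assembles equity tables of richest-versus-poorest, urban-versus-rural
    and education-stratified risk ratios.  Includes a synthetic
    household-survey generator with known ground-truth inequity so the full
    pipeline is testable without restricted survey microdata.
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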