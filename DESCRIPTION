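Package: pfnr
Title: PrEP Facility-to-Need Ratios for Geographic HIV Prevention Access
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible geospatial pipeline for quantifying geographic
    access to HIV preexposure prophylaxis (PrEP). Assigns point facilities
    (PrEP-prescribing locations and pharmacies) to polygonal analysis units
    (ZIP code tabulation areas or counties) by point-in-polygon containment,
    computes per-unit PrEP facility-to-need ratios (PFNRs) against 5-year HIV
    incidence per 100 000 persons, summarizes PFNR distributions per region,
    estimates the fold increase in availability from expanding PrEP provision
    to pharmacies, detects facility deserts, and renders incidence choropleths
    with facility overlays. Includes a synthetic-scenario generator with known
    ground truth (clustered prescriber point processes, dense homogeneous
    pharmacy processes, lognormal incidence surfaces with optional small-area
    suppression) so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
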