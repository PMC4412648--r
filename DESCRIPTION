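Package: luefusion
Title: Light-Use-Efficiency Productivity Modelling and Carbon-Use-Efficiency Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing and integrating satellite-driven
    light-use-efficiency (LUE) estimates of vegetation productivity with
    dynamic-vegetation-model (DVM) products over a land-cover-stratified
    domain. Implements a MOD17-style daily GPP engine with autotrophic
    respiration partitioning and annual NPP, a gap-fill quality-control
    metric, coarse-to-fine grid harmonization, land-cover zonal statistics
    in petagrams of carbon, a carbon-use-efficiency (NPP/GPP) fusion that
    applies DVM respiration fractions to fine-grid LUE GPP, point-site
    validation against in-situ aboveground NPP, and seeded synthetic-data
    generators emulating an African-style study domain so the full pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
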