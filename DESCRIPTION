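Package: radsurvey
Title: Car-Borne Gamma-Ray Survey Analysis and Environmental Radiological
    Hazard Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction of absorbed dose rate in air from shielded
    car-borne NaI(Tl) count rates, activity concentrations of the U-238
    series, Th-232 series and K-40 by response-matrix unfolding of pulse
    height spectra and by the HPGe absolute-efficiency soil assay, annual
    effective doses and radiological hazard indices (radium equivalent
    activity, external hazard index), and the direct-versus-soil dose-rate
    comparison that quantifies shielding and source effects of the built-up
    environment. Includes a synthetic survey-campaign generator with known
    ground truth, minimum-curvature gridding of dose-rate surfaces, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
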