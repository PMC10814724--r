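Package: kdecho
Title: Coronary Artery Z-Scores for Murine Kawasaki Disease Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal echocardiographic surveillance of
    coronary artery lesions in the Lactobacillus casei cell wall extract
    (LCWE) mouse model of Kawasaki disease. Fits a day-0 normative model of
    vessel diameter indexed to the square root of body surface area,
    computes echocardiographic Z-scores, classifies coronary artery lesions
    at the Z > 3 cutoff, and derives the weight-adjusted diameters and wall
    thickness measures used in dose-response and carotid-coronary
    association analyses. A seeded synthetic-cohort generator emulates the
    study design (dose groups, measurement days, normative ranges,
    dose- and time-dependent dilation) so every pipeline stage is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
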