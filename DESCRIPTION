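Package: pupilfield
Title: Light-Adapted Pupil Size Analysis for Wearable Spectral and Pupillometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for field studies of the light-adapted pupil:
    alpha-opic photometry from spectral irradiance (conservative 1 nm rebinning,
    photopic illuminance, five alpha-opic irradiances and equivalent daylight
    illuminances including melanopic EDI), a data-quality cascade with a
    scree-based participant-exclusion threshold, linear mixed-model hypothesis
    tests scored by BIC-approximated log10 Bayes factors, age-effect regressions
    across light-level clusters, the Watson-Yellott unified pupil-size formula,
    and a physically motivated synthetic-data generator (blackbody/daylight,
    LED and fluorescent illuminants; age-dependent log-linear pupil model) so
    the full pipeline is testable without wearable recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
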