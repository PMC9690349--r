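Package: thermorqa
Title: Recurrence Quantification Analysis of Diurnal Skin-Temperature Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear recurrence quantification analysis (RQA) of wearable-sensor
    skin-temperature time series, with the statistical layer of a paired cross-over
    field study: Takens delay embedding, recurrence-plot construction with a
    radius set as a fraction of the mean pairwise phase-space distance,
    diagonal/vertical line-length statistics (recurrence rate, determinism,
    laminarity, entropy, divergence, trend, mean line lengths), eligibility
    filtering of raw sensor records, paired comparison of log-transformed RQA
    metrics between settings, a principal-component composite, and linear
    mixed-effects models linking RQA metrics to urinary metabolic hormones.
    Includes a synthetic cohort generator emulating diurnal skin-temperature
    dynamics so the full pipeline is reproducible without sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    lme4,
    lmerTest,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
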