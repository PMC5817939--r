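Package: reefbleach
Title: High-Resolution Thermal-Stress Indices and Optimized Coral Bleaching Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting coral bleaching from gridded sea-surface
    temperature and ancillary environmental fields. Builds per-cell SST
    climatologies (maximum monthly mean with trend recentering, mean annual
    maximum, interannual variability), computes accumulated thermal-stress
    indices (degree heating weeks and months, degree cooling weeks) with
    tunable hotspot filtering thresholds, fits binomial-logit and
    random-forest bleaching models, optimizes evaluation and filtering
    thresholds by true-skill-statistic maximization under repeated
    train/test cross-validation, and maps predicted bleaching probability
    and frequency, including a UV-screening management scenario. A fully
    parameterized synthetic-data generator with known ground truth supports
    end-to-end testing without satellite archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    geosphere,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
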