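Package: salimend
Title: Saline-Soil Amendment Analytics: Soil Quality Index, Microbial
    Networks and Path Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible analysis pipeline for saline-soil amendment
    field trials: electrical-conductivity to total-dissolved-solids
    calibration, min-max indicator scoring and a PCA-communality-weighted
    Soil Quality Index (SQI), amplicon abundance-table analytics (alpha
    diversity estimators, Bray-Curtis ordination, rank aggregation),
    treatment-wise microbial co-occurrence networks with topology and
    modularity reports, environmental-driver attribution by Spearman
    screens and random-forest variance explained, and partial least
    squares path modeling (PLS-PM) linking treatment, soil, microbes and
    yield. Includes a seeded synthetic-study generator emulating a
    three-treatment (control, biochar, surfactant-modified biochar) field
    design so the whole chain runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    multcomp,
    randomForest,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
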