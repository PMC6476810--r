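Package: jewelcox
Title: Survival-Based Scoring of Smartphone Trail-Making Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores smartphone trail-making ("jewels") cognitive assessments
    by treating the per-tap event sequence of each game as event times in a
    survival model. Each game is compared against a control-derived reference
    path with a two-group Cox proportional-hazards fit under administrative
    censoring based on the game difficulty level, log hazard ratios are
    adjusted for level and mistake category through a linear mixed model, and
    per-subject summaries ("beta values") are formed by inverse-variance
    weighting, study-wide and in weekly windows. Includes a synthetic-study
    generator with companion weekly survey and step-count streams, group
    comparison of beta values, and per-subject weekly cross-stream
    correlation matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    lme4,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
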