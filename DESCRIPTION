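Package: LocoNLMM
Title: Non-Linear Mixed Effects Modelling of Rodent Locomotor Activity
    After Irradiation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal locomotor-activity data from
    irradiated rodents. Builds nightly activity summaries from raw infrared
    movement counts, fits a non-linear mixed effects model with crossed
    animal and day random effects by direct maximum likelihood, performs
    AIC-based submodel selection, predicts random effects by posterior
    means, and summarises the radiation dose-response (initial decrease in
    activity and its recovery rate) with delta-method confidence intervals.
    Includes a model-exact synthetic-data generator for validation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'LocoNLMM-package.R'
    'model-core.R'
    'fitting.R'
    'dose-response.R'
    'ingest.R'
    'simulate.R'
    'pipeline.R'
    'random-effects.R'
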