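Package: pcdeff
Title: Design Effects and Sample Size for Partially Clustered Trials
Version: 0.1.0
Authors@R: person("pcdeff", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Design effects, sample size planning and simulation-based
    validation for two-arm parallel partially clustered randomized trials
    with pre-existing clusters of varying sizes (e.g., singletons, twins
    and triplets in neonatal trials, or repeated enrolments in
    re-randomization designs), analysed by generalized estimating
    equations with an independence or exchangeable working correlation
    structure. Provides closed-form design effects for continuous and
    binary outcomes under cluster or individual randomization, general
    allocation-based forms, a direct matrix evaluation of the sandwich
    covariance, cluster-size distribution conversions, recruitment
    target calculations, expected power, generators for exchangeable
    correlated continuous and binary outcomes, and a scenario-grid
    simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
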