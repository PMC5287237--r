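Package: gpgrowth
Title: Gaussian Process Modeling and Differential Testing of Microbial Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric Gaussian process (GP) regression for microbial
    population growth curves measured by plate-reader optical density.
    Extracts growth parameters (maximum specific growth rate, carrying
    capacity, area under the curve with exact posterior uncertainty) from
    fitted GPs via derivative GPs; fits the four classical primary growth
    models (Gompertz, logistic, Schnute, Richards) as parametric baselines
    with a held-out mean-squared-error benchmark; tests for differential
    growth between strains and strain-by-stress interactions with
    approximate Bayes factors calibrated by per-time-point label
    permutation (empirical false-discovery-rate control); computes
    baseline-corrected per-time-point posterior growth contrasts; and
    corrects cross-study batch effects with a hierarchical two-level GP.
    Includes a synthetic growth-data generator with known ground truth and
    a command-line workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
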