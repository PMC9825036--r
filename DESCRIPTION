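Package: msmcal
Title: Calibrated Inverse Probability Weights for Marginal Structural
    Models with Irregular Visits
Version: 0.1.0
Authors@R:
    person("UTOPIAN", "Methods", email = "methods@example.org",
           role = c("aut", "cre"))
Description: Estimation of marginal causal effects of time-varying
    treatments on longitudinal outcomes observed at irregular visit times,
    in the possible presence of a subject-specific unmeasured confounder.
    Provides a discrete-time data-generating simulator with
    treatment-confounder and visit-confounder feedback, stabilized inverse
    probability of treatment and of visit weights from pooled logistic
    models, covariate-balance calibration of those weights by exponential
    tilting (with unity-mean and per-subject latent-confounder moment
    restrictions, solved by a Barzilai-Borwein spectral method), weighted
    generalized estimating equations with AR(1) working correlation and
    robust sandwich variance, a Monte Carlo G-computation oracle for the
    true marginal effect, and an orchestrator for multi-scenario
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
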