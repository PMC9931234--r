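Package: illdyn
Type: Package
Title: Illness-State Transition Entropy and Dynamic Phenotypes for
    Critical-Care Admissions
Version: 0.1.0
Authors@R: person("Sam", "Keller", email = "sam.keller@example.org",
    role = c("aut", "cre"))
Description: Characterizes individual illness dynamics in intensive-care
    admissions from continuous illness-severity risk scores. Scores sampled
    on a 15-minute grid are resampled to 30 minutes, filtered to adjacent
    pairs, and binned into discrete illness states; per-admission Markov
    transition count, probability, and joint transition-density matrices
    are summarized by the Shannon entropy of the transition density.
    Entropy values are clustered with Ward's method into dynamic
    phenotypes, and their association with a min-tie rank composite of
    negative outcomes (mortality, ventilator days, hospital stay) is
    estimated by linear regression with restricted-cubic-spline adjustment
    for mean illness score. A seeded synthetic-cohort generator provides
    ground-truth chains and outcome tables for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
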