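Package: crtcompliance
Title: Treatment Non-Compliance in Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying treatment
    non-compliance in two-arm cluster randomized trials with a continuous
    outcome. Generates two-level trial data in which the probability of
    never-taking the intervention depends on a cluster- or subject-level
    covariate, analyzes each simulated trial by intention-to-treat,
    as-treated, per-protocol and instrumental-variable (two-stage least
    squares with cluster-robust standard errors) approaches, and evaluates
    mean estimate, efficiency, confidence-interval coverage and empirical
    power across a factorial grid of intraclass correlation, cluster size
    and non-compliance conditions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    sandwich,
    optparse,
    withr
Config/testthat/edition: 3
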