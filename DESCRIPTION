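Package: acsmarkov
Title: Markov Modeling of Hospital Addiction Consult Services and
    12-Month Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and validates a single-cycle Markov (decision-tree)
    model of hospital-based addiction consult service care for patients
    hospitalized with opioid use disorder: referral to a consult
    service, post-discharge treatment engagement under a modified HEDIS
    claims rule, and 12-month drug-related and non-drug-related
    mortality.  Includes a seeded synthetic claims-data generator,
    claims-style cohort measures (eligibility, engagement and cause-of-
    death classification, matched-control construction), expert-
    elicitation beta priors expressed as pseudo-data, Bayesian logistic
    regression for transition probabilities with convergence
    diagnostics and Pareto-smoothed importance-sampling leave-one-out
    model comparison, and expected-count cohort projections with
    deterministic low/high bound scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
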