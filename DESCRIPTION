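Package: xenoeq
Title: Equipoise Analysis for Kidney Xenotransplant Candidate Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic toolkit for asking which kidney-waitlist candidates
    reach clinical equipoise between accepting a xenotransplant with an assumed
    graft survival of n years and remaining on the allotransplant waitlist.
    Provides a seeded synthetic registry generator emulating the statistical
    structure of waitlist data (covariate-dependent death/delisting and
    transplant hazards, post-transplant survival, relisting after graft failure,
    and center-level marginal-organ offer behaviour); survival model fitting
    (Cox proportional hazards, random survival forests, Kaplan-Meier) with
    restricted-mean life expectancy; an equipoise engine with sensitivity
    analysis over the assumed xenograft survival; cohort and center
    "aggressiveness" analysis; counterfactual allocation-incentive scenarios via
    a discrete-time semi-Markov recursion; hit-rate/capture-rate evaluation; and
    a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
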