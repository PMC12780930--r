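Package: adolgraft
Title: Donor-Recipient Age Mismatch and Allocation Simulation for Adolescent Liver Transplants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying donor-recipient age mismatch in adolescent
    liver transplantation with synthetic registry data. Provides a seeded
    generator emulating a national transplant registry (confounded exposure
    assignment, piecewise-exponential graft survival with a late-emerging
    exposure effect, hospital geography), cohort derivation with the study's
    inclusion rules and derived covariates (Du Bois body-surface-area index,
    graft size classes, center volume tertiles), 1:1 nearest-neighbor
    propensity-score matching with caliper and balance diagnostics,
    Kaplan-Meier / log-rank / Cox landmark survival analysis, and a
    counterfactual reallocation simulation of adolescent donor grafts under
    travel-distance ceilings with 90th-percentile wait summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    survival,
    jsonlite,
    readr,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
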