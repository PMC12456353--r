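Package: sbipcatchup
Title: School-Based Immunization Catch-Up Coverage and Deficit Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveillance of school-based immunization programs from
    linked administrative registry tables. Builds grade-year cohorts under
    age and enrollment eligibility rules, computes month-aligned cumulative
    vaccine coverage with binomial confidence intervals against a prepandemic
    counterfactual cohort, stratifies dose administration into routine and
    catch-up volumes by school-year and summer periods, and projects the time
    required to clear cumulative immunization deficits from observed annual
    catch-up uptake. Includes a synthetic-registry simulator with a
    closed-form discrete-time hazard oracle so every pipeline stage can be
    validated against known ground truth without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
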