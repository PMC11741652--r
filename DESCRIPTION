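Package: testfuse
Title: Aggregating Repeated Binary Diagnostic Test Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for combining the results of repeated binary diagnostic or
    screening tests with Boolean aggregation rules. Computes exact
    sensitivity and specificity of arbitrary rules (AND, OR, majority,
    k-of-n, truth tables, Boolean expressions) under conditional
    independence, enumerates all rules for small test panels and extracts
    the efficient ROC frontier, quantifies the test economy of series
    versus parallel administration, applies a generalized Rogan-Gladen
    correction to measured prevalences and derives infection fatality and
    hospitalization ratios, bounds rule characteristics without any
    independence assumption via Boole-Frechet inequalities, estimates
    pairwise dependence factors from raw cohort data, propagates
    uncertainty through any pipeline quantity by beta-distribution Monte
    Carlo, and simulates synthetic testing cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
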