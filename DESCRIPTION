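Package: vmmccost
Title: Unit-Cost Curves and Cross-Country Extrapolation for Voluntary
    Medical Male Circumcision Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the average cost per voluntary medical male
    circumcision (VMMC) across facilities and service delivery platforms in
    sub-Saharan Africa.  Standardizes heterogeneous facility-level cost
    records into comparable 2016 US dollars, aggregates them to service
    delivery platforms, fits log-linear and gamma log-link unit-cost curves
    that capture economies of scale, extrapolates unit costs with uncertainty
    to platforms and countries without data, and validates extrapolations by
    leave-one-country-out cross-validation.  A calibrated synthetic-data
    generator reproduces the statistical structure of multi-country VMMC
    costing data so the full pipeline can be exercised and tested without
    access to restricted facility datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lmtest,
    sandwich,
    withr
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
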