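Package: mrix
Title: Margin Risk Index Scoring and Survival Validation for
    Post-Immunochemotherapy Surgical Margins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a biology-based re-definition of surgical margin status
    in head and neck squamous cell carcinoma treated with neoadjuvant
    immunochemotherapy. Converts raw margin biomarkers (tertiary lymphoid
    structure density, Pan-CK foci, Ki-67, driver mutations, PD-L1 RNA,
    CD8+/FoxP3+ ratio, Granzyme B) into four 0/1/2 domain scores and the
    weighted Margin Risk Index (MRIx) with a close-margin override; simulates
    proportional-hazards cohorts with configurable marginal frequencies and
    effect sizes; and provides from-scratch survival kernels (Kaplan-Meier
    with Greenwood variance, k-sample log-rank, Cox regression with Efron tie
    handling, Harrell's concordance index, likelihood-ratio model comparison,
    Breslow baseline hazard, fixed-horizon Hosmer-Lemeshow calibration, and
    Benjamini-Hochberg adjustment) together with the cohort-analysis and
    frozen-score external-validation workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
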