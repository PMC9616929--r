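Package: healthindex
Title: Polygenic Health Index Construction and Selection Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Combines per-disease polygenic risk scores into a composite
    health index expressed in estimated life years, and validates it with
    selection experiments.  Provides a calibrated liability-threshold
    simulator for cohorts of unrelated individuals and genetic sibling
    pairs and trios, the two-Gaussian mixture model converting a polygenic
    score to absolute disease risk, index construction with life-year or
    disability-adjusted (DALY) weights, group and within-family selection
    experiments with relative-risk-reduction and index-gain metrics and
    bootstrap or Wilson-score confidence intervals, quantile-prevalence
    profiles, and characterization of pairwise comorbidity and PRS-level
    genetic correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
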