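Package: pedmetref
Title: Age- and Sex-Dependent Reference Percentiles and Association
    Analyses for Pediatric Metabolite Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates age- and sex-dependent reference percentile curves
    for blood metabolite panels (amino acids, acylcarnitines) using the
    LMS method under Box-Cox Cole-Green (BCCG) and Box-Cox t (BCT)
    distributions fitted by spline maximum likelihood, with family-aware
    resampling to handle sibling clusters and repeated visits. Provides
    standard-deviation-score (SDS) conversion, quality-control filters
    (limit-of-detection exclusion, log-scale outlier removal), hierarchical
    random-intercept association analyses against BMI-SDS, Tanner stage and
    laboratory markers with Benjamini-Yekutieli false-discovery-rate
    control, and a synthetic-cohort generator emulating the longitudinal,
    family-clustered structure of pediatric cohort studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
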