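Package: pedmets
Title: Cardiometabolic Indices and Metabolic Syndrome Screening in
    Pediatric Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes twelve pediatric cardiometabolic indices (BMI and
    BMI-SDS, tri-ponderal mass index, fat-mass and fat-free-mass indices,
    body mass fat index, a body shape index, visceral adiposity index,
    waist-to-height ratio, cardiometabolic index, and the lipid ratios
    TC/HDL-C and TG/HDL-C) together with HOMA-IR; diagnoses metabolic
    syndrome with age-dispatched IDEFICS (7 to <10 y) and IDF (10 to <16 y,
    16+ y) criteria against injectable percentile references; and evaluates
    each index as a screening test via empirical ROC curves, rank-based AUC
    with DeLong confidence intervals and paired comparison, Youden-optimal
    cutoffs, predictive values and likelihood ratios, and sliding-window
    age- and sex-specific cutoff trends. Ships a synthetic cohort generator
    emulating a Prader-Willi-like pediatric population with a latent
    cardiometabolic risk state, so the full analysis runs end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
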