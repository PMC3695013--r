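Package: brainage
Title: Brain-Age Estimation from Gray-Matter MRI and Prognosis of
    MCI-to-AD Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates an individual's brain age from a gray-matter
    structural MRI map using principal component analysis and relevance
    vector regression trained on healthy controls, and derives the
    brain-age gap (BrainAGE) score, the difference between estimated and
    chronological age. Includes the full prognostic evaluation layer used
    to assess conversion of mild cognitive impairment to Alzheimer's
    disease: ROC curves with paired DeLong AUC comparison, McNemar tests,
    diagnostic accuracy with Wald confidence intervals, likelihood ratios
    and post-test probabilities, Cox proportional-hazards regression and
    Kaplan-Meier curves. A synthetic cohort generator produces gray-matter
    phantoms with age-dependent decline and hazard-linked conversion times
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
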