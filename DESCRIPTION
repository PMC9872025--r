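Package: hoopdev
Title: Specialization Onset, Maturation and Physical Fitness Development in
    Youth Basketball
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether early sport specialization confers a
    physical-fitness advantage in youth basketball. Provides maturation-referenced
    classification of specialization onset and somatic maturity status (age at
    peak height velocity from age-by-stature offset equations), pooled z-score
    composite fitness scoring with line-drill reversal, Bayesian hierarchical
    models of within-season change (cross-classified varying intercepts and
    slopes) and developmental change (three-level quadratic growth curves)
    fitted with JAGS, posterior prediction grids with 68% credible ribbons,
    specialization contrasts, convergence diagnostics, posterior predictive
    checks, and a synthetic longitudinal cohort generator with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
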