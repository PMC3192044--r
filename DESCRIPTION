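Package: growthseam
Title: Smoothly-Joining Two-Phase Growth Models for Cross-Sectional
    Age-Morphometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits, simulates and inverts growth curves for animals with two
    distinct growth phases, motivated by macropod (pouch / post-pouch)
    morphometry.  The core model (SJ2P) joins a Verhulst logistic pouch-phase
    curve to a Brody post-pouch curve with value and slope continuity at the
    join age; the join age itself is estimated by residual-sum-of-squares
    profiling.  Also provides the single-curve comparator families (logistic,
    Brody, Brody with offset, von Bertalanffy, linear, post-pouch log
    hyperbola), per-phase goodness-of-fit statistics, a two-cohort
    cross-sectional data simulator, inverse prediction of age from a
    measurement, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
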