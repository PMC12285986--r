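Package: vividmem
Title: Visual Imagery Vividness, Short-Term Memory and Regional Brain Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for extreme-groups studies of visual imagery
    vividness (VVIQ), object-location visual short-term memory and regional
    brain volumes. Provides a seeded synthetic-cohort generator (subjects,
    trial-level task data under a target/misbinding/guessing mixture, and
    region-by-side volume tables), the resampling-based trial classifier that
    turns placement responses into per-trial misbinding and guessing
    probabilities, extreme-groups selection with boundary-tie expansion,
    split-plot mixed ANOVA with Type III sums of squares and partial eta
    squared, Bayesian single-case inference against a control sample with a
    Crawford-Howell closed-form oracle, and composite tests (Fisher's method,
    ordering and sign-consistency binomials, 2x2 chi-squared with Yates
    correction). A pipeline function runs the full simulate-score-design-test
    analysis and emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
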