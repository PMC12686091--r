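Package: implicitprecision
Title: Individual-Level Measurement Precision of Implicit Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the measurement precision of individual scores on
    implicit measures (IAT, Brief IAT, Single-Target IAT, AMP, GNAT,
    Evaluative Priming Task). Scores trial-level data with the
    probabilistic index (common-language effect size), places basic
    (reverse-percentile) bootstrap confidence intervals around each
    participant's score, derives three precision statistics per
    measure-by-domain cell (detectability from the neutral point,
    pairwise discriminability between participants, and confidence
    interval coverage of the observed score range), compares measures
    with inverse-variance-weighted mixed-effects meta-analysis and
    Holm-corrected contrasts of estimated marginal means, and provides
    standard-error-of-measurement utilities for precision planning.
    Includes a seeded trial-level simulator with known ground-truth
    effects so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
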