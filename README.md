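# implicitprecision

Individual-level measurement precision of implicit measures.

Implicit measures (IAT, Brief IAT, Single-Target IAT, AMP, GNAT,
Evaluative Priming Task) are widely used to make claims about single
individuals — "this person shows a moderate bias", "these two people
differ". Those claims require knowing how precisely a *single
participant's* score is measured, which group-level reliability cannot
tell you. This package quantifies that precision directly from each
participant's own trial-level data and compares measures on a common
footing.

The pipeline:

1. **Scoring.** Every task is scored with the probabilistic index
   (PI) — the probability that a random response from one condition
   pool exceeds one from the other, ties counted half:
   `PI = (#{b > a} + ½·#{b = a}) / (nA·nB)`, the Mann–Whitney U scaled
   to [0, 1], with 0.5 the point of zero effect. IAT-family D scores
   and other native scores are also available.
2. **Per-participant bootstrap CIs.** Each participant's trials are
   resampled (2000 resamples, stratified by block role) and a basic
   (reverse-percentile) 95% interval `(2θ̂ − Q₀.₉₇₅, 2θ̂ − Q₀.₀₂₅)` is
   placed around their score.
3. **Three precision statistics** per measure × domain cell:
   detectability (CI excludes PI = 0.5), discriminability (proportion
   of other participants a person's score is detectably different
   from), and coverage (CI width over the observed score range).
4. **Meta-analytic comparison.** Each statistic is modelled as
   `y ~ 1 + measure + (1 | domain), weights = 1/variance` (REML via
   lme4), with estimated marginal means per measure and Holm-corrected
   pairwise contrasts.
5. **Precision planning.** SEm utilities (`SEm = SD·√(1−r)`), the
   algebra of CI widths needed to separate feedback cut-offs, and a
   simulation-based error-rate planner for comparing two individuals.

A seeded trial-level simulator with known ground-truth effects makes
the whole pipeline testable without external data.

## Worked example

```r
library(implicitprecision)

cfg <- study_config(n_participants = 50,
                    bootstrap = bootstrap_spec(n_resamples = 2000),
                    seed = 20260929)
bundle <- run_precision_study(cfg)
summarize_report(bundle)
```

```
Precision study summary (seed 20260929, 2000 resamples, metric PI)
  AMP    modal CI width 0.222 | detectable 0.439 | discriminable 0.123 | coverage 0.591
  BIAT   modal CI width 0.360 | detectable 0.275 | discriminable 0.089 | coverage 0.608
  EPT    modal CI width 0.326 | detectable 0.342 | discriminable 0.056 | coverage 0.721
  GNAT   modal CI width 0.289 | detectable 0.472 | discriminable 0.086 | coverage 0.655
  IAT    modal CI width 0.203 | detectable 0.554 | discriminable 0.118 | coverage 0.564
  STIAT  modal CI width 0.290 | detectable 0.370 | discriminable 0.102 | coverage 0.648
  largest detectability contrast: BIAT - IAT = -0.279 (Holm p = 4.5e-05)
```

Reading: even in a cohort with a real average effect, a typical 95% CI
spans a fifth to a third of the PI scale (`modal CI width`); barely half
of IAT takers — and far fewer for the other tasks — have intervals that
exclude the neutral point (`detectable`); and any one participant is
statistically distinguishable from only about a tenth of their peers
(`discriminable`). The IAT, with the largest trial budget, is the most
precise; the Brief IAT the least — the trial-count mechanism the
package is built to expose. On this synthetic cohort 94.1% of the
intervals covered the participant's true PI, confirming calibration
(every participant's true score is known by construction).

The planner answers the design question directly:

```r
required_widths(cutoff_scheme())
#>       from       to cutoff_low cutoff_high required_width
#> 1  no_bias     weak       0.00        0.15            0.3
#> 2     weak moderate       0.15        0.35            0.4
#> 3 moderate   strong       0.35        0.65            0.6
```

To separate even the widest pair of adjacent Project Implicit feedback
categories, an individual's D-score CI must be narrower than 0.6 — while
the narrowest published cut-off interval has width 0.58, right at that
limit.

The numbered scripts under `analysis/` run these steps end to end
(`01_simulate_study.R`, `02_precision_study.R`,
`03_precision_planning.R`), writing their tables under `results/`.

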