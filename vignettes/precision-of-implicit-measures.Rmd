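---
title: "Quantifying individual-level precision of implicit measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual-level precision of implicit measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implicitprecision)
```

## The problem

Implicit measures — the IAT and its brief and single-target variants,
the AMP, the GNAT, and evaluative priming — are routinely used to make
claims about *individual* people: that this participant shows a
moderate bias, that one a strong bias, that two participants differ.
Such claims presuppose that a single participant's score is measured
precisely enough to support them. Group-level reliability statistics do
not answer that question, because they assume every individual's score
carries the same error. This package estimates the measurement
precision of each individual's score directly, from that individual's
own trial-level data, and compares measures on that basis.

## Scoring: the probabilistic index

All six tasks are scored with the same metric so they can be compared
on one scale. The probabilistic index (PI; also known as the
common-language effect size or Ruscio's A) is the probability that a
randomly chosen response from one condition pool exceeds a randomly
chosen response from the other, ties counted half:

$$\mathrm{PI} = \frac{\#\{(a,b): b > a\} + \tfrac12\,\#\{b = a\}}{n_A\, n_B},$$

which is the Mann–Whitney U statistic scaled to $[0, 1]$; 0.5 is the
neutral point of zero effect. `pi_score()` computes it through midranks
in $O(n \log n)$; the test suite keeps a brute-force pair enumeration
as an oracle. The orientation convention makes role B the
bias-consistent pool, so PI > 0.5 and D > 0 read in the same
direction. Native scores are also provided: the IAT-family D score
(`d_score()`, mean latency difference over the inclusive SD of all
critical trials, both roles pooled, $n-1$ denominator), the AMP
proportion difference, and the plain latency difference. Error-trial
latencies are retained by default (`use_error_trials` in
`score_spec()`), since tasks administered with built-in error
correction fold the penalty into the recorded latency; the flag exists
for administrations that do not.

## Per-participant bootstrap intervals

Each participant's trial-level data are resampled with replacement
(2000 resamples by default), the score recomputed on each resample, and
a **basic (reverse-percentile) interval** formed:

$$\left(2\hat\theta - Q_{1-\alpha/2},\; 2\hat\theta - Q_{\alpha/2}\right),$$

with $Q$ the type-7 empirical quantile of the replicates. Numerical
choices, fixed for reproducibility:

* **Stratified resampling by block role** is the default: the PI and D
  need both pools, and unstratified resampling can produce an empty
  one. Unstratified resampling is available behind a flag; invalid
  resamples are redrawn at most 100 times and then dropped with a
  warning, which bounds runtime on pathological inputs.
* **Quantile rule** is fixed to type 7 so that intervals are identical
  across platforms and sessions.
* **Bounds are not clipped** to the metric's range. A basic interval
  for a PI can extend below 0 or above 1; that is information about the
  resampling distribution, and any clipping is an explicit opt-in
  post-step.
* **Seeding**: the global study seed spawns a substream per
  (participant, measure, domain) through a deterministic string hash,
  so results do not depend on the order participants appear in the
  input.

Pairwise comparisons between participants reuse each participant's
cached replicate vector, paired index by index. For independently
generated streams this is statistically equivalent to a fresh bootstrap
of the difference and avoids an $O(n^2)$ re-bootstrapping cost.

## The three precision statistics

For each measure × domain cell:

1. **Detectability** — the proportion of participants whose 95% CI
   excludes the neutral point (PI = 0.5). A bound exactly on the null
   does not count. Its variance is binomial, $p(1-p)/n$.
2. **Discriminability** — for each participant, the proportion of the
   other participants in the cell from whom their score is detectably
   different (the difference CI excludes 0), over $n-1$ partners, with
   a binomial variance over $n-1$. The relation is symmetric under the
   shared replicate pairing. These individual-level proportions (not a
   cell aggregate) are the rows of the corresponding meta-analysis.
3. **Coverage** — each participant's CI width divided by the observed
   range of point estimates in the cell; the cell summary is the mean
   width proportion with the variance of the mean. "Observed range" is
   read as the range of point estimates; reading it as the span of all
   interval bounds is also defensible, and the per-cell range is a
   single divisor, so switching readings rescales but does not reorder
   cells. Width proportions above 1 are legal and preserved.

Proportions of exactly 0 or 1 and variances of exactly 0 are offset by
0.001 (to 0.001, 0.999, and 0.001 respectively) so every row can carry
an inverse-variance weight. The 0.999 direction for $p = 1$ is a
symmetric interior nudge. The modal CI width per cell (`map_width()`)
is the mode of a Gaussian kernel density estimate over the widths
(Silverman bandwidth, 2048-point grid between the sample extremes) —
deterministic and smooth, unlike a histogram mode.

## Meta-analytic comparison of measures

Each statistic's rows are entered into

$$y \sim 1 + \mathrm{measure} + (1 \mid \mathrm{domain}),
\qquad \mathrm{weights} = 1/\mathrm{variance},$$

fitted by REML (`lme4`). Measure is a fixed, exhaustive factor; domain
is a random intercept, since attitude domains are a sample from a
larger population of domains. Weights are treated as known *relative*
error variances with a residual scale estimated — the standard reading
of weighted mixed models. Two numerical contracts:

* With fewer than two domain levels, or when $\hat\tau^2 \le 10^{-10}$,
  the fit reduces to weighted least squares and is flagged
  `"WLS-fallback"`. With only three domain levels $\tau^2$ is weakly
  identified, so the flag is part of the public interface rather than
  hidden.
* Estimated marginal means are linear combinations of the fixed
  effects (the random intercept averages to zero), and all pairwise
  contrasts use a standard-normal reference for their p-values, Holm
  step-down corrected (`stats::p.adjust`). A z reference was chosen
  over a Satterthwaite/Kenward–Roger approximation for determinism and
  because the contrasts here are descriptive; with very few domains it
  is mildly anticonservative, which is documented rather than patched.

## SEm utilities and precision planning

The standard error of measurement, $\mathrm{SEm} = SD\sqrt{1-r}$,
yields $\pm 1.96\,\mathrm{SEm}$ intervals around an individual score
(`sem()`, `sem_interval()`). `required_ci_width()` inverts the
feedback-category question: a score at one cut-off excludes an adjacent
cut-off only if its symmetric CI is narrower than twice the gap — 0.6,
0.4 and 0.3 D-score units for the strong/moderate, moderate/weak and
weak/none gaps of the Project Implicit scheme.
`simulate_error_rates()` turns a per-score measurement SD into false
positive and false negative rates for comparing two individuals, using
the $\sqrt2$ error inflation of a difference of two noisy scores; its
false-negative rate matches the closed-form two-sided normal power, a
cross-check in the test suite. `dscore_cutoff_intervals()` summarizes
bootstrap D intervals of participants whose estimates fall within a
tolerance of each cut-off (median bounds by default); this
neighborhood-summary construction is one defensible reading of how
such cut-off interval tables can be produced, and every knob
(tolerance, summary functional) is exposed.

## What the synthetic generator emulates — and what it does not

The generator exists so every downstream stage has a testable ground
truth; it is not an attempt to mimic empirical Project Implicit
distributions. Defaults:

* **Latency noise** is ex-Gaussian (Gaussian sd 100 ms + exponential
  tail mean 150 ms on a 600 ms base) — the standard minimal RT model
  with a right tail; parameters are exposed so heavier tails can be
  probed.
* **The condition effect** enters latencies additively: role-B trials
  are shifted by a participant-specific $\delta_i \sim
  N(\mu_\delta, \tau_\delta^2)$ (defaults 60 ± 40 ms, a moderate
  population effect with real heterogeneity). Binary (AMP-like) tasks
  shift a Bernoulli probability on the logit scale (defaults 0.8 ± 0.6
  log-odds), which keeps probabilities in range.
* **Trial budgets** mirror the tasks' relative critical-trial counts
  (IAT 60/60, Brief IAT 20/20, single-target and go/no-go variants
  30/30, priming 24/24, AMP 36/36), reproducing the central mechanism
  that precision grows with trial count.
* **True PI**: for Gaussian shifts, $\Phi(\delta/(\sigma\sqrt2))$; for
  binary tasks, the four-outcome enumeration; for ex-Gaussian noise
  the exponential components difference is Laplace, and the PI is a
  one-dimensional integral of the normal CDF against a Laplace
  density, evaluated by adaptive quadrature (`integrate`, relative
  tolerance $10^{-10}$) — deterministic and faster than Monte-Carlo
  evaluation, which the tests retain only as an oracle.

Not emulated: empirical score distributions of any real dataset,
sequence effects, practice/fatigue drift, response-process structure
(no diffusion-style model), correlations between measures within a
participant, or realistic missingness. Passing tests therefore show
that the *pipeline machinery* is correct and calibrated under a
well-behaved generative model — not that any particular real measure
attains a given precision.

## Exclusion policy

The default policy follows common IAT-family practice: retain trials
in a 300–10000 ms window; drop a participant unit when more than 10%
of latencies are under 300 ms, when accuracy over non-missing trials
falls below 0.80 (tasks without a correct answer record accuracy as
missing and are exempt), or when a role pool retains fewer than 2
trials. The fast-trial proportion is evaluated before window trimming
so anticipatory responses are counted. All thresholds are explicit
`exclusion_policy()` fields and documented as assumptions, not claims
about any particular study's criteria.

## Problem sizes and calibration evidence

The test suite's simulation checks use sizes chosen to give tight
Monte-Carlo tolerances at desk runtimes: interval calibration on 500
synthetic participants (200 trials/role, true PIs 0.5/0.6/0.75, 2000
resamples) — coverage within 3 Monte-Carlo SEs of 0.95 and null
detectability within 3 SEs of 0.05; monotone precision across
20/80/320 trials per role (60 participants); meta-model parameter
recovery over 100 replicates; error-rate planner checks at $10^5$
simulated pairs. The end-to-end study in `analysis/` runs 6 measures ×
3 domains × 50 participants with 2000 resamples in a few minutes on
one CPU and reproduces byte-identically under a fixed seed.

## Known limitations

* The basic bootstrap is first-order accurate; for very small trial
  counts (the Brief IAT template) its coverage can dip below nominal.
  The percentile method is available for comparison; BCa is not an
  acceptance surface here.
* RQ2's per-participant variance uses the binomial form over $n-1$
  comparisons, which ignores the dependence among pairs sharing a
  participant; it is a weight, not an inferential variance.
* With three domains, $\tau^2$ estimates are noisy; treat
  random-intercept variances descriptively.
* z-based contrast p-values are mildly anticonservative for few
  domains (see above).
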