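---
title: "Modelling enrollment-timing effects on child physical fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enrollment-timing effects on child physical fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrollfit)
```

## The problem

School cohorts are assembled by birthdate against a legal enrollment cutoff
(September 30 in the population this package models). A third-grade
classroom therefore contains *keyage* children -- aged 8y0m to 8y11m at the
cutoff -- alongside *older-than-keyage* (OTK) children who were enrolled
late or repeated a grade, and *younger-than-keyage* (YTK) children enrolled
early or who skipped a grade. Because physical fitness rises steeply with
age in this range, raw comparisons between these groups conflate enrollment
history with ordinary growth. `enrollfit` implements a pipeline that
separates the two: it learns the age-, sex-, school- and year-graded
expectation of performance from the keyage children alone, predicts what
each non-keyage child *would* score if they followed the keyage development
curve, and analyses the per-child difference -- the **delta z-score** -- as
the outcome of interest.

The battery is five tests: a 6-min endurance run (metres, recorded to 9 m),
a star-run coordination course (50.912 m, time to 0.1 s), a 20-m sprint
(time to 0.1 s), a standing long jump (cm), and a 1-kg ball push (0.1 m).

## The pipeline, stage by stage

**Enrollment classification.** Group labels are a pure function of
birthdate and the cutoff date of the assessment year, by *completed years
at the cutoff* (exact month/day comparison): 7 completed years is YTK, 8
keyage, 9 OTK; 6 or fewer and 10 or more are excluded from analysis. A
child born exactly on the cutoff has completed the year. The decimal age
used as the model covariate is different: day count from birthdate to test
date divided by 365.25. The two definitions deliberately coexist -- a
YTK child tested in late November can be slightly older than 8.0 years --
and children whose decimal age crosses a band boundary are *not*
reassigned.

**Pace scores.** Timed tests are converted to course length over time
(m/s), so that larger is better on every test. A Box-Cox profile
(`boxcox_diagnostic()`) of timed scores from this kind of battery selects an
exponent near -1; the reciprocal-style pace transformation is therefore
applied unconditionally to the timed tests, and the diagnostic is exposed
as an advisory check only.

**Two-stage standardization.** Stage 1 computes z-scores within test x sex
x enrollment-group cells -- single pass, cell mean and n-1 SD from the full
cell -- and removes observations whose |z| strictly exceeds `k = 3`
(`|z| = k` is retained). Statistics are not recomputed after removal.
Removal defaults to the offending row; `scope = "child"` removes the whole
child, which is the accounting used by the exclusion ledger. Stage 2
re-standardizes pace scores against the keyage per-test mean and SD, so a
keyage cohort has mean 0 and SD 1 per test by construction and non-keyage
scores are expressed in keyage units. Stage-2 statistics pool the sexes by
default, because sex enters every downstream model as a fixed effect;
`by_sex = TRUE` is available for sensitivity analysis.

**The keyage reference model.** Stage-2 keyage z-scores are fitted with a
linear mixed model with crossed random effects:

* fixed: grand mean; four sequential-difference test contrasts H1-H4
  (coordination-endurance, speed-coordination, powerLOW-speed,
  powerUP-powerLOW); age, linear, centered at 8.5 years; sex coded
  girl = -1/2, boy = +1/2; and all interactions;
* random: grand mean + H1-H4 per **child** (correlated); grand mean +
  H1-H4 + sex + age per **school** (correlated); independent per-test and
  age components per **assessment year**.

The age term is linear only: predictions for 7- and 9-year-olds are linear
extrapolations, and carrying a quadratic learned on a one-year age window
into a one-year extrapolation would let curvature noise dominate. The
quadratic lives in the delta models instead, where the non-keyage data can
support it.

**Prediction and deltas.** The expected score of a non-keyage child is the
reference fixed part plus the conditional modes (BLUPs) of their school and
assessment year when those levels occurred in the keyage fit; new levels
contribute zero, and child effects always contribute zero (the children
are new by construction). The delta is the exact arithmetic difference
observed minus predicted. Because school and year modes are absorbed into
the prediction, the delta models need far less random-effect structure
than the reference. A fixed-part-only prediction
(`re_include = character()`) is available for sensitivity analysis.

**Group delta models.** OTK: fixed grand mean, H1-H4, linear + quadratic
age (centered 8.5), sex, and the age x contrast and sex x contrast
interactions (higher-order interactions are excluded from the default);
random: per-test child components with correlations, independent per-test
+ age school components, year intercept. YTK: fixed grand mean + contrasts
only; random per-test child components with correlations and independent
per-test school components -- the structure a group an order of magnitude
smaller can support. Both defaults are ordinary `lmm_spec()` objects, so
any alternative specification can be supplied and the selection procedure
reproduced rather than taken on faith.

**Interpretation conventions.** A fixed effect is flagged when
|z| = |estimate/SE| strictly exceeds 2.0, two-sided, with no
multiple-testing correction and no denominator-degrees-of-freedom
adjustment. With thousands of children these conventions are
indistinguishable from t-based ones; the threshold is exposed as a
constant rather than buried.

**Random-structure selection.** `select_random_structure()` walks a nested
lattice greedily using REML likelihood-ratio tests at alpha = 0.05:
backward drops (component blocks, correlation switches, whole factors)
are accepted when the test does not reject; forward additions are accepted
only when the test rejects *and* the enlarged fit converged without
singularity -- an overparameterized fit is treated as unsupported by the
data, not as evidence. Chi-square reference p-values are conservative when
the dropped component sits on a variance boundary, which biases selection
toward simpler structures; that is the intended direction. The trace
records every comparison as deviances, degrees of freedom and p-values
only -- fixed-effect estimates are never consulted during selection.

**Post-hoc nested parameterization.** After a group model is chosen, sex
(and age, for OTK) can be re-estimated *within* each test level
(`posthoc_nested_fit()`), replacing main effects + interactions by five
directly interpretable per-test coefficients. On a common span the two
parameterizations give identical fitted values; the nested form answers
"is there a sex difference in the long jump?" without contrast algebra.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage above is testable with
known ground truth. It emulates: three enrollment groups with birthdates
uniform in the band implied by the cutoff; five tests per child with 3%
missingness; linear age trends (0.45-0.55 z/year) and boys-girls
differences (0.25-0.74 z) per test; equicorrelated child effects
(variance 0.9, correlation 0.5 across tests), school effects (variance
0.08, plus a 0.01 school-level age-slope variance), an assessment-year
intercept (0.03) and residual variance 0.65; group delta profiles -- an
OTK deficit with linear (-1.014/year) and quadratic (+0.357/year^2) age
structure and a YTK advantage largest on coordination; recording at
instrument precision; and heavy child-relative-to-school variance. Scores
are written in raw instrument units, so the generator exercises the pace
transformation and both standardization stages, not just the models.

Default sizes are 3,000 keyage + 800 OTK + 100 YTK children in 40 schools
over 3 assessment years -- large enough that variance components are
identified, small enough that a replicated simulation study runs in
minutes. Proportion-based sampling (1.9% / 78.8% / 19.3%) is available for
full-population-scale draws.

Randomness uses one root seed split into per-stage streams (schools,
years, children, child effects, residuals, missingness), so enlarging the
child sample does not perturb the school or year draws.

**Scale bookkeeping.** Generator parameters are expressed on the latent z
scale. The fitted pipeline standardizes by the *empirical* keyage SD
(stage 2), which exceeds 1 on the latent scale because child, school, year
and residual variation all contribute. Fitted quantities are therefore
generating quantities multiplied by an exactly known per-test factor, and
`ground_truth_standardized()` performs that conversion; parameter-recovery
tests compare on the converted scale. This is bookkeeping, not a free
parameter.

What the generator does **not** emulate: best-of-two-trial measurement
(scores represent the recorded best trial), longitudinal retesting of the
same child, biological-maturation covariates, non-Gaussian score
distributions beyond what quantization induces, and informative
missingness. Passing tests therefore validate the pipeline's arithmetic
and statistical calibration, not the behavioural realism of any particular
cohort.

## Numerical choices

Model fitting is delegated to `lme4::lmer` (profiled REML over relative
Cholesky factors, crossed grouping factors, sparse normal equations),
behind a declarative `lmm_spec()` layer that owns contrast construction,
design ordering, interaction materialization, nesting checks and
extraction. Three deliberate settings:

* `check.nobs.vs.nRE` is relaxed: the battery design estimates a
  5-dimensional child term from at most five observations per child, which
  is identified through the pooled covariance structure; the default guard
  rejects exactly this legitimate design.
* the finite-difference convergence check (`calc.derivs`) is disabled --
  with ~50 covariance parameters it costs more than the optimization and
  its warnings on boundary fits are not actionable; singularity is
  reported instead (`isSingular`), and boundary estimates are admissible
  outcomes, not errors.
* optimizer: NLopt BOBYQA, `xtol_abs = 1e-7`, `ftol_abs = 1e-7`,
  `maxeval = 1e5`.

Replicated simulation studies (tests and the acceptance script) use two
further documented economies: tolerances loosened to `xtol_abs = 1e-5`
(Monte-Carlo noise dominates long before that), warm starts carried
between replicates (start values cannot move a REML optimum, only reach it
faster), and a reference model whose school block is diagonal (no school
correlation parameters). The school correlations are nuisance structure
for every quantity those studies recover -- generalized-least-squares
fixed effects remain consistent under the simpler weighting -- and the
28-parameter school factor is by far the worst-conditioned part of the
full reference at simulation sample sizes. Production fits
(`fit_keyage_reference()` defaults) keep the full correlated structure.

Degenerate inputs are first-class: zero-variance stage-1 cells error
naming the cell; boundary variance estimates are flagged, not rejected;
a zero-noise cohort must round-trip to deltas that are numerically zero
(this is a test); the likelihood-ratio statistic is clipped at zero
against optimizer jitter.

## Known limitations

* The keyage reference extrapolates linearly outside the 8-9 band; with
  cross-sectional data there is no way to validate the extrapolation
  against observed keyage children of those ages.
* Assessment-year components are estimated from very few levels (three in
  the default simulations, nine in a full survey); their variance
  estimates are routinely at or near the boundary and should be read as
  absorbed nuisance, not as estimates of a year effect.
* Deltas inherit reference-model estimation error, which is not
  propagated into the delta-model standard errors -- the same convention
  as the two-stage analysis the package implements. With a keyage group
  an order of magnitude larger than the target groups, the neglected term
  is second-order.
* Selection by repeated boundary-conservative LRTs has no formal
  family-wise guarantee; it is a reproducible, auditable procedure, not
  an inferential one.
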