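# enrollfit

Does the *timing* of school enrollment — being older or younger than the
expected age band for one's grade — go along with differences in physical
fitness? `enrollfit` implements the full analysis pipeline for that
question in third-grade cohorts tested with a five-test battery (6-min
endurance run, star-run coordination course, 20-m sprint, standing long
jump, 1-kg ball push), for researchers in pediatric exercise science and
epidemiology working with school-based surveillance data.

## The analysis

Children are classified by completed years of age at the enrollment
cutoff (September 30): 8 completed years is **keyage**, 9 is
**older-than-keyage (OTK)**, 7 is **younger-than-keyage (YTK)**; anyone
outside 7–9 is excluded, with an auditable ledger. Timed tests are
converted to pace scores (course length / time, m/s) so that larger is
better everywhere, then standardized in two stages: cell-wise z-scores
within test × sex × group with removal of |z| > 3 outliers, followed by
standardization against the keyage per-test mean and SD.

The keyage children alone determine a reference linear mixed model for
the standardized score *z* of child *i*, test *t*:

    z_it = β₀ + Σⱼ βⱼ Hⱼ(t) + β_a·a_i + β_s·s_i + (interactions)
           + u_child(i) + u_school(i) + u_year(i) + ε_it

with sequential-difference test contrasts H1–H4 (coordination−endurance,
speed−coordination, powerLOW−speed, powerUP−powerLOW), age *a* centered
at 8.5 years (linear), sex *s* coded girl = −½ / boy = +½, and crossed
random effects: correlated grand-mean + contrast terms by child,
correlated grand-mean + contrasts + sex + age terms by school, and
independent per-test + age components by assessment year (REML via
lme4).

Each non-keyage child's expected score is the reference fixed part —
extrapolated linearly in age — plus the conditional modes (BLUPs) of
their school and assessment year. The **delta z-score**

    Δ_it = z_it(observed) − ẑ_it(predicted)

is then modelled per group: for OTK with grand mean, contrasts, a
quadratic age polynomial, sex and their contrast interactions; for YTK
with grand mean and contrasts only. Fixed effects are read with the
|z| > 2 convention; the random-effect structure can be selected by a
deviance-only parsimonious procedure (`select_random_structure()`), and
sex/age effects re-estimated per test with a nested parameterization
(`posthoc_nested_fit()`).

A synthetic cohort generator (`generate_cohort()`) with fully
retrievable ground truth — enrollment bands, age and sex gradients,
group delta profiles, child/school/year variance components, instrument
quantization, missingness — makes every stage testable end to end.

## Worked example

```r
library(enrollfit)

cfg <- synth_config(group_sizes = c(keyage = 1200, otk = 400, ytk = 60),
                    n_schools = 25)
gen <- generate_cohort(cfg, seed = 7)

tab  <- annotate_cohort(gen$table)          # group + decimal age
excl <- apply_exclusions(tab)               # age bands, health flags
st1  <- stage1_filter(add_pace(excl$table)) # cell-wise |z| > 3 removal
append_outlier_stage(excl$ledger, st1$n_removed_children, st1$n_removed_rows)
#>   stage    children  rows
#> 1 initial      1660  8058
#> 2 age             0     0
#> 3 health         -4   -20
#> 4 outlier       -10   -10
#> 5 retained     1646  8028

tab <- st1$table
ref <- reference_stats(tab[tab$group == "keyage", ])
tab <- stage2_standardize(tab, ref)

reference <- fit_keyage_reference(tab[tab$group == "keyage", ], ref)
otk    <- tab[tab$group == "otk", ]
deltas <- compute_deltas(otk, predict_expected(reference, otk))
dplyr::summarise(dplyr::group_by(deltas, test), mean_delta = round(mean(delta), 2))
#>   test         mean_delta
#> 1 endurance         -0.33
#> 2 coordination      -0.04
#> 3 speed             -0.1
#> 4 power_low         -0.12
#> 5 power_up          -0.07

fit <- fit_group_model(deltas, "otk")
fit$fixed[1:8, ]
#>          term estimate    se      z significant
#> 1 (Intercept)    0.164 0.445  0.367       FALSE
#> 2          H1    0.018 0.849  0.022       FALSE
#> 3          H2    0.454 0.828  0.549       FALSE
#> 4          H3    0.330 0.779  0.424       FALSE
#> 5          H4    0.089 0.813  0.109       FALSE
#> 6        ageL   -0.382 0.872 -0.438       FALSE
#> 7        ageQ    0.093 0.404  0.229       FALSE
#> 8        sexc    0.017 0.065  0.261       FALSE
```

The mean deltas are negative — the simulated OTK children underperform
the keyage expectation at their ages, by construction of the generator's
delta profile — and the model's grand mean (0.16 ± 0.45 at the 8.5-year
centering origin) brackets the generating value on the standardized
scale (0.263, from `ground_truth_standardized()`); at this desk-scale
sample the age terms are individually noisy because the intercept and
age polynomial extrapolate back from a one-year age window. The whole
sequence above is `run_pipeline()`, which also writes the descriptives,
fixed-effect, variance-component and delta tables, ledger and selection
trace to an output directory; a shell wrapper lives at
`inst/scripts/enrollfit-pipeline.R`.

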