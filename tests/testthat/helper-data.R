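# Fixture builders shared across test files. Everything is generated in code.

# thin alias: the exclusion-stream builder lives in the package
ledger_fixture <- function(n_clean, n_outlier = 0, n_health = 0,
                           n_age_excluded = 0, group = "otk", year = 2011,
                           seed = 1) {
  synthesize_exclusion_stream(n_clean, n_outlier, n_health, n_age_excluded,
                              group = group, year = year, seed = seed)
}

# run the standardization + reference + delta stages on a generated cohort
pipeline_deltas <- function(gen, ref_spec = NULL, control = NULL,
                            start_ref = NULL) {
  tab <- annotate_cohort(gen$table)
  tab <- apply_exclusions(tab)$table
  tab <- add_pace(tab)
  tab <- stage1_filter(tab)$table
  key <- tab[tab$group == "keyage", ]
  ref <- reference_stats(key)
  tab <- stage2_standardize(tab, ref)
  key <- tab[tab$group == "keyage", ]
  rf <- fit_keyage_reference(key, ref, spec = ref_spec, start = start_ref,
                             control = control)
  nonkey <- tab[tab$group %in% c("otk", "ytk"), ]
  deltas <- compute_deltas(nonkey, predict_expected(rf, nonkey))
  list(table = tab, keyage = key, ref = ref, reference = rf, deltas = deltas)
}

# keyage reference structure with the school block diagonal: the simulation
# studies use this variant (school correlation parameters are nuisance
# structure for the recovered quantities and the fits are much better
# conditioned at simulation sample sizes)
sim_reference_spec <- function() {
  spec <- fitness_model_spec("keyage_reference")
  spec$random$school <- re_block(c("1", paste0("H", 1:4), "sexc", "ageL"),
                                 cp = FALSE)
  spec
}

# loosened optimizer tolerances for replicated simulation fits
sim_control <- function() {
  lme4::lmerControl(optimizer = "nloptwrap", calc.derivs = FALSE,
                    check.nobs.vs.nRE = "ignore",
                    optCtrl = list(xtol_abs = 1e-5, ftol_abs = 1e-6,
                                   maxeval = 1e5))
}

# delta records drawn directly from the OTK delta-model generative process
# (per-test child effects, school effects, year intercept, residual), for
# engine-level parameter recovery where generating values live on the fitted
# scale directly
simulate_delta_table <- function(n_children, n_schools, n_years = 3,
                                 gm_profile = rep(0, 5),
                                 age_lin = 0, age_quad = 0, sex_diff = rep(0, 5),
                                 child_vc = 0.9, child_corr = 0.5,
                                 school_vc = 0.08, year_vc = 0.03,
                                 resid_vc = 0.65, ages = c(9, 10), seed = 1) {
  set.seed(seed)
  tests <- battery_tests()
  Sig <- child_vc * ((1 - child_corr) * diag(5) + child_corr)
  ev <- eigen(Sig, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  child_re <- matrix(rnorm(n_children * 5), n_children) %*% t(L)
  school_re <- matrix(rnorm(n_schools * 5, 0, sqrt(school_vc)), n_schools)
  year_re <- rnorm(n_years, 0, sqrt(year_vc))
  school_of <- sample(n_schools, n_children, TRUE)
  year_of <- sample(n_years, n_children, TRUE)
  sex_of <- sample(c(-0.5, 0.5), n_children, TRUE)
  age_of <- runif(n_children, ages[1], ages[2])
  ci <- rep(seq_len(n_children), each = 5)
  ti <- rep(1:5, n_children)
  ageL <- age_of[ci] - 8.5
  delta <- gm_profile[ti] + age_lin * ageL + age_quad * ageL^2 +
    sex_diff[ti] * sex_of[ci] +
    child_re[cbind(ci, ti)] + school_re[cbind(school_of[ci], ti)] +
    year_re[year_of[ci]] + rnorm(length(ci), 0, sqrt(resid_vc))
  tibble::tibble(
    child_id = sprintf("C%05d", ci),
    school_id = sprintf("S%03d", school_of[ci]),
    assessment_year = 2010 + year_of[ci],
    sex = factor(ifelse(sex_of[ci] > 0, "boy", "girl"), c("girl", "boy")),
    test = factor(tests[ti], tests),
    age_years = age_of[ci],
    delta = delta
  )
}
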