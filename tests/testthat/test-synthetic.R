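small_cfg <- function(...) {
  synth_config(group_sizes = c(keyage = 150, otk = 60, ytk = 25),
               n_schools = 8, years = 2011:2012, ...)
}

test_that("generation is deterministic from config and seed", {
  g1 <- generate_cohort(small_cfg(), seed = 99)
  g2 <- generate_cohort(small_cfg(), seed = 99)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$truth$child_effects, g2$truth$child_effects)
  g3 <- generate_cohort(small_cfg(), seed = 100)
  expect_false(identical(g1$table$raw_value, g3$table$raw_value))
})

test_that("school and year draws are unaffected by the number of children", {
  g_small <- generate_cohort(small_cfg(), seed = 5)
  g_big <- generate_cohort(
    synth_config(group_sizes = c(keyage = 400, otk = 100, ytk = 40),
                 n_schools = 8, years = 2011:2012), seed = 5)
  expect_identical(g_small$truth$school_effects, g_big$truth$school_effects)
  expect_identical(g_small$truth$year_effects, g_big$truth$year_effects)
})

test_that("the zero-noise degenerate cohort yields exactly zero deltas", {
  cfg0 <- synth_config(
    group_sizes = c(keyage = 150, otk = 60, ytk = 30),
    n_schools = 4, years = 2011:2012,
    delta_otk = rep(0, 5), delta_ytk = rep(0, 5),
    otk_age = c(linear = 0, quadratic = 0),
    child_vc = 0, school_vc = 0, school_age_vc = 0, year_vc = 0,
    resid_vc = 0, child_corr = 0, school_corr = 0,
    missingness = 0, health_rate = 0, quantize = FALSE)
  g0 <- generate_cohort(cfg0, seed = 3)
  res <- pipeline_deltas(g0)
  expect_lt(max(abs(res$deltas$delta)), 1e-8)
})

test_that("disabling quantization makes the transforms exactly invertible", {
  cfg <- small_cfg(quantize = FALSE, missingness = 0)
  g <- generate_cohort(cfg, seed = 21)
  tab <- add_pace(annotate_cohort(g$table))
  ref_cfg <- cfg$ref_raw
  z <- stage2_standardize(tab, ref_cfg)$z2
  expect_lt(max(abs(z - g$truth$rows$latent_z)), 1e-10)
})

test_that("quantization is at instrument precision", {
  g <- generate_cohort(small_cfg(), seed = 13)
  defs <- test_definitions()
  for (i in seq_len(nrow(defs))) {
    x <- g$table$raw_value[g$table$test == defs$test[i]]
    expect_lt(max(abs(x / defs$precision[i] -
                        round(x / defs$precision[i]))), 1e-8)
  }
})

test_that("missingness thins rows at the configured rate", {
  cfg <- synth_config(group_sizes = c(keyage = 2000, otk = 0, ytk = 0),
                      n_schools = 10, years = 2011:2013, missingness = 0.03)
  g <- generate_cohort(cfg, seed = 31)
  rate <- 1 - nrow(g$table) / 10000
  expect_lt(abs(rate - 0.03), 0.01)
})

test_that("realized random-effect variances match the configured components", {
  cfg <- synth_config(group_sizes = c(keyage = 5000, otk = 0, ytk = 0),
                      n_schools = 100, years = 2011:2013)
  g <- generate_cohort(cfg, seed = 41)
  child_mat <- as.matrix(g$truth$child_effects[, battery_tests()])
  school_mat <- as.matrix(g$truth$school_effects[, battery_tests()])
  expect_lt(abs(mean(apply(child_mat, 2, var)) / 0.9 - 1), 0.1)
  expect_lt(abs(mean(apply(school_mat, 2, var)) / 0.08 - 1), 0.1)
  # between-test correlation of child effects near the configured 0.5
  cm <- cor(child_mat)
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.5), 0.05)
})

test_that("group sampling by probability hits the study proportions", {
  cfg <- synth_config(n_children = 137421,
                      group_probs = c(ytk = 0.019, keyage = 0.788, otk = 0.193),
                      n_schools = 100, years = 2011:2013)
  g <- generate_cohort(cfg, seed = 8)
  counts <- table(g$truth$children$group)
  # binomial 99% bounds around the calibration counts 2586/108296/26540
  for (grp in c("ytk", "keyage", "otk")) {
    p <- cfg$group_probs[grp]
    bound <- 2.576 * sqrt(137421 * p * (1 - p))
    expect_lt(abs(counts[[grp]] - 137421 * p), bound + 1)
  }
})

test_that("planted outliers behave as designed around the k = 3 threshold", {
  cfg <- synth_config(group_sizes = c(keyage = 1500, otk = 500, ytk = 0),
                      n_schools = 20, years = 2011:2012, missingness = 0)
  g <- generate_cohort(cfg, seed = 17)
  tab <- annotate_cohort(g$table)

  res0 <- inject_outliers(tab, rate = 0, magnitude = 5)
  expect_identical(res0$table, tab)

  res5 <- inject_outliers(tab, rate = 0.01, magnitude = 5, seed = 2)
  st <- stage1_filter(add_pace(res5$table), k = 3)
  planted_key <- paste(res5$planted$child_id, res5$planted$test)
  removed_key <- paste(st$removed$child_id, st$removed$test)
  expect_gte(mean(planted_key %in% removed_key), 0.95)

  res25 <- inject_outliers(tab, rate = 0.005, magnitude = 2.5, seed = 3)
  st25 <- stage1_filter(add_pace(res25$table), k = 3)
  planted_key <- paste(res25$planted$child_id, res25$planted$test)
  removed_key <- paste(st25$removed$child_id, st25$removed$test)
  expect_lte(mean(planted_key %in% removed_key), 0.05)
})
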