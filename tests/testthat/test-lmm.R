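one_way_data <- function(values, groups) {
  tibble::tibble(y = values, g = factor(groups))
}

test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  # 3 groups x 2 replicates: MSW = 2, MSB = 32, between VC = (32-2)/2 = 15
  d <- one_way_data(c(0, 2, 4, 6, 8, 10), rep(1:3, each = 2))
  spec <- lmm_spec("y", random = list(g = re_block("1")))
  fit <- fit_lmm(d, spec)
  expect_equal(fit$fixed$estimate[1], 5, tolerance = 1e-6)
  expect_equal(fit$sigma2, 2, tolerance = 1e-5)
  expect_equal(fit$vc$variance[fit$vc$factor == "g"], 15, tolerance = 1e-4)
  expect_false(fit$singular)
})

test_that("identical group means force the between variance to the boundary", {
  d <- one_way_data(c(1, 3, 1, 3, 1, 3), rep(1:3, each = 2))
  spec <- lmm_spec("y", random = list(g = re_block("1")))
  fit <- fit_lmm(d, spec)
  expect_equal(fit$vc$variance[fit$vc$factor == "g"], 0, tolerance = 1e-8)
  expect_true(fit$singular)
})

test_that("crossed designs match the dense brute-force REML oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    f1 <- rep(1:4, each = 6)
    f2 <- rep(rep(1:3, each = 2), 4)
    y <- rnorm(4, 0, 1.5)[f1] + rnorm(3, 0, 1)[f2] + rnorm(24)
    d <- tibble::tibble(y = y, g1 = factor(f1), g2 = factor(f2))
    spec <- lmm_spec("y", random = list(g1 = re_block("1"), g2 = re_block("1")))
    fit <- fit_lmm(d, spec)

    oracle <- dense_reml_fit(y, matrix(1, 24),
                             list(indicator_matrix(f1), indicator_matrix(f2)))
    expect_equal(fit$deviance, oracle$deviance, tolerance = 1e-6)
    expect_equal(fit$fixed$estimate[1], oracle$beta, tolerance = 1e-4)
    expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-4)
    vc_fit <- c(fit$vc$variance[fit$vc$factor == "g1"],
                fit$vc$variance[fit$vc$factor == "g2"])
    expect_equal(vc_fit, unname(oracle$vc), tolerance = 1e-4)
  }
})

test_that("REML deviance is invariant to row order and level relabeling", {
  set.seed(5)
  f1 <- sample(1:5, 60, TRUE)
  f2 <- sample(1:4, 60, TRUE)
  x <- runif(60)
  y <- 1 + x + rnorm(5, 0, 1)[f1] + rnorm(4, 0, 0.7)[f2] + rnorm(60, 0, 0.5)
  d <- tibble::tibble(y = y, x = x, g1 = factor(f1), g2 = factor(f2))
  spec <- lmm_spec("y", fixed = "x",
                   random = list(g1 = re_block("1"), g2 = re_block("1")))
  fit <- fit_lmm(d, spec)

  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  d2$g1 <- factor(letters[as.integer(as.character(d2$g1))])
  fit2 <- fit_lmm(d2, spec)
  expect_equal(fit$deviance, fit2$deviance, tolerance = 1e-7)
  expect_equal(fit$fixed$estimate, fit2$fixed$estimate, tolerance = 1e-5)
})

test_that("CP-off specifications produce diagonal covariance by construction", {
  d <- simulate_delta_table(120, 10, seed = 6)
  spec <- lmm_spec("delta",
                   random = list(child_id = re_block(paste0("T_", battery_tests())),
                                 school_id = re_block("1")))
  des <- build_design(d, spec)
  fit <- fit_lmm(des$data, spec)
  expect_equal(nrow(fit$cp), 0)
  expect_equal(sum(fit$vc$factor == "child_id"), 5)
  # z-values are exactly estimate/SE
  expect_equal(fit$fixed$z, fit$fixed$estimate / fit$fixed$se)
})

test_that("predictions combine the fixed part with selected conditional modes", {
  set.seed(8)
  n_per <- 30
  sch <- rep(1:2, each = n_per)
  x <- runif(2 * n_per, -1, 1)
  y <- 2 + 0.8 * x + c(-0.6, 0.6)[sch] + rnorm(2 * n_per, 0, 0.4)
  d <- tibble::tibble(y = y, x = x, school = factor(sch))
  spec <- lmm_spec("y", fixed = "x", random = list(school = re_block("1")))
  fit <- fit_lmm(d, spec)

  nd <- tibble::tibble(x = c(0, 1, 0, 0),
                       school = c("1", "1", "2", "99"))
  p_fix <- predict(fit, nd, re_include = character())
  p_re <- predict(fit, nd, re_include = "school")
  beta <- fit$fixed$estimate
  # fixed-only prediction at x = 0 is the intercept; slope adds linearly
  expect_equal(p_fix[1], beta[1], tolerance = 1e-8)
  expect_equal(p_fix[2] - p_fix[1], beta[2], tolerance = 1e-8)
  # unknown level contributes zero
  expect_equal(p_re[4], p_fix[4], tolerance = 1e-10)
  # conditional modes match the closed-form normal equations
  X <- cbind(1, nd$x[1])
  theta <- fit$theta
  modes <- dense_modes(theta, beta, y, cbind(1, x),
                       list(indicator_matrix(sch)))[[1]]
  expect_equal(p_re[1] - p_fix[1], unname(modes[1]), tolerance = 1e-4)
  expect_equal(p_re[3] - p_fix[3], unname(modes[2]), tolerance = 1e-4)
  expect_error(predict(fit, nd, re_include = "nope"), "not grouping factors")
})

test_that("the likelihood-ratio test is deviance-based with boundary flag", {
  d <- simulate_delta_table(100, 8, seed = 10)
  des <- build_design(d, lmm_spec("delta"))
  s0 <- lmm_spec("delta", random = list(child_id = re_block("1")))
  s1 <- lmm_spec("delta", random = list(child_id = re_block("1"),
                                        school_id = re_block("1")))
  f0 <- fit_lmm(des$data, s0)
  f1 <- fit_lmm(des$data, s1)
  same <- lrt(f0, f0)
  expect_equal(same$statistic, 0)
  expect_equal(same$df, 0)
  t01 <- lrt(f0, f1)
  expect_gte(t01$statistic, 0)
  expect_equal(t01$df, 1)
  expect_true(t01$boundary)
  # non-nested specs error
  s2 <- lmm_spec("delta", random = list(school_id = re_block("1")))
  f2 <- fit_lmm(des$data, s2)
  expect_error(lrt(f2, f1), NA)   # s2 random is a subset of s1's factors
  s3 <- lmm_spec("delta", fixed = "sexc", random = list(school_id = re_block("1")))
  des3 <- build_design(d, s3)
  f3 <- fit_lmm(des3$data, s3)
  expect_error(lrt(f0, f3), "not nested|not comparable|refit")
})

test_that("boundary-null LRT is conservative and detects real components", {
  # full model adds one between-group VC whose generating value is 0:
  # rejection at nominal 0.05 stays at or below 0.05 (chi-square is
  # conservative on the boundary)
  set.seed(77)
  n_sim <- 120
  rej_null <- 0
  g <- factor(rep(1:10, each = 6))
  spec0 <- lmm_spec("y", random = list())
  spec1 <- lmm_spec("y", random = list(g = re_block("1")))
  for (i in seq_len(n_sim)) {
    y <- rnorm(60)
    d <- tibble::tibble(y = y, g = g)
    # intercept-only "nested" model fitted by lm gives the REML criterion
    # analytically; use lmer for the full and compare via the engine
    f1 <- fit_lmm(d, spec1)
    # REML criterion of the no-RE model: profile closed form
    r <- y - mean(y)
    rss <- sum(r^2)
    dev0 <- 1 * log(2 * pi) * 0 + # constant folded below
      (59) * (1 + log(2 * pi * rss / 59)) + log(60)
    stat <- max(0, dev0 - f1$deviance)
    if (pchisq(stat, 1, lower.tail = FALSE) < 0.05) rej_null <- rej_null + 1
  }
  expect_lte(rej_null / n_sim, 0.06)

  # large generating VC: LRT rejects essentially always at moderate n
  rej_alt <- 0
  for (i in 1:10) {
    gg <- factor(rep(1:20, each = 10))
    y <- rnorm(20, 0, 1.5)[gg] + rnorm(200)
    d <- tibble::tibble(y = y, g = gg)
    f1 <- fit_lmm(d, lmm_spec("y", random = list(g = re_block("1"))))
    r <- y - mean(y)
    dev0 <- 199 * (1 + log(2 * pi * sum(r^2) / 199)) + log(200)
    stat <- max(0, dev0 - f1$deviance)
    if (pchisq(stat, 1, lower.tail = FALSE) < 0.05) rej_alt <- rej_alt + 1
  }
  expect_gte(rej_alt / 10, 0.95)
})
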