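test_that("pace transformation follows the course-length formulas", {
  expect_equal(to_pace("coordination", 25.456), 2.0)
  expect_equal(to_pace("speed", 4.0), 5.0)
  expect_equal(to_pace("endurance", 1041), 1041)
  expect_error(to_pace("speed", 0), "nonpositive time")
  expect_error(to_pace("nosuch", 1), "unknown test")
  # inverse round trip on all tests
  set.seed(1)
  for (tt in battery_tests()) {
    x <- runif(50, 1, 100)
    expect_equal(from_pace(tt, to_pace(tt, x)), x, tolerance = 1e-12)
  }
  # monotonicity: smaller time => larger pace for timed tests
  times <- sort(runif(20, 3, 30))
  expect_true(all(diff(to_pace("coordination", times)) < 0))
})

test_that("Box-Cox profile identifies reciprocal and identity transforms", {
  set.seed(101)
  base <- rnorm(5000, 10, 1.5)
  recip <- 1 / base[base > 0]
  expect_lt(abs(boxcox_diagnostic(recip)$lambda_hat - (-1)), 0.2)
  norm_pos <- rnorm(5000, 50, 5)
  expect_lt(abs(boxcox_diagnostic(norm_pos)$lambda_hat - 1), 0.2)
  expect_error(boxcox_diagnostic(rep(3, 100)), "degenerate")
  expect_error(boxcox_diagnostic(c(-1, rexp(20))), "positive")
})

make_cell_table <- function(values, test = "endurance", sex = "boy",
                            group = "otk") {
  n <- length(values)
  tibble::tibble(
    child_id = sprintf("C%03d", seq_len(n)),
    school_id = "S001", assessment_year = 2011L,
    sex = factor(sex, c("girl", "boy")),
    test = factor(test, battery_tests()),
    group = factor(group),
    pace_value = values
  )
}

test_that("stage-1 z-scores use single-pass cell statistics with n-1 SD", {
  res <- stage1_filter(make_cell_table(c(2, 4, 6)), k = 3)
  expect_equal(res$table$z1, c(-1, 0, 1))
  expect_equal(res$n_removed_rows, 0)

  # the 9-zeros-plus-100 cell: z of the outlier is 2.846; retained at k = 3,
  # removed at k = 2.8
  vals <- c(rep(0, 9), 100)
  z_out <- (100 - mean(vals)) / sd(vals)
  expect_equal(round(z_out, 2), 2.85)
  expect_equal(stage1_filter(make_cell_table(vals), k = 3)$n_removed_rows, 0)
  res28 <- stage1_filter(make_cell_table(vals), k = 2.8)
  expect_equal(res28$n_removed_rows, 1)
  expect_equal(res28$removed$pace_value, 100)

  expect_error(stage1_filter(make_cell_table(rep(5, 4))), "degenerate")
})

test_that("stage-1 z-scores have mean 0, SD 1 per cell before filtering", {
  set.seed(7)
  tab <- dplyr::bind_rows(
    make_cell_table(rnorm(40, 10), sex = "boy"),
    make_cell_table(rnorm(35, 12), sex = "girl"),
    make_cell_table(rnorm(30, 5), test = "speed")
  )
  res <- stage1_filter(tab, k = Inf)
  cells <- split(res$table$z1,
                 interaction(res$table$test, res$table$sex, drop = TRUE))
  for (z in cells) {
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
  # after filtering at finite k no retained |z1| exceeds k
  res3 <- stage1_filter(tab, k = 1.5)
  expect_true(all(abs(res3$table$z1) <= 1.5))
})

test_that("child-scope removal drops every row of a flagged child", {
  tab <- dplyr::bind_rows(
    make_cell_table(c(rep(0, 9), 100)),
    make_cell_table(rnorm(10, 5), test = "speed")
  )
  # same child ids across the two tests
  res <- stage1_filter(tab, k = 2.8, scope = "child")
  flagged <- "C010"
  expect_false(flagged %in% res$table$child_id)
  expect_equal(res$n_removed_rows, 2)
  expect_equal(res$n_removed_children, 1)
})

test_that("stage-2 standardization uses the keyage reference statistics", {
  ref <- tibble::tibble(test = battery_tests(),
                        mean = c(1000, 2, 4.5, 125, 3.7),
                        sd = c(150, 0.3, 0.4, 19, 0.7))
  tab <- make_cell_table(c(1000, 1150, 850))
  out <- stage2_standardize(tab, ref)
  expect_equal(out$z2, c(0, 1, -1))
  bad <- tab
  expect_error(stage2_standardize(bad, ref[-1, ]), "missing from reference")

  # keyage rows standardized against their own statistics: mean 0, SD 1
  set.seed(3)
  key <- dplyr::bind_rows(lapply(battery_tests(), function(tt)
    make_cell_table(rnorm(60, 10, 2), test = tt, group = "keyage")))
  ref2 <- reference_stats(key)
  out2 <- stage2_standardize(key, ref2)
  for (tt in battery_tests()) {
    z <- out2$z2[out2$test == tt]
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  }
})

test_that("reference stats reject degenerate SDs and support sex cells", {
  key <- make_cell_table(rep(5, 10), group = "keyage")
  expect_error(reference_stats(key), "non-positive")
  set.seed(4)
  key2 <- dplyr::bind_rows(
    make_cell_table(rnorm(30, 10), sex = "boy", group = "keyage"),
    make_cell_table(rnorm(30, 12), sex = "girl", group = "keyage")
  )
  r <- reference_stats(key2, by_sex = TRUE)
  expect_equal(nrow(r), 2)
  out <- stage2_standardize(key2, r)
  for (s in c("girl", "boy")) {
    expect_lt(abs(mean(out$z2[out$sex == s])), 1e-12)
  }
})
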