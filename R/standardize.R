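#' Add pace scores to an observation table
#'
#' @param table Observation table with `test` and `raw_value`.
#' @return The table with a `pace_value` column ([to_pace()] of each row).
#' @export
add_pace <- function(table) {
  table$pace_value <- to_pace(as.character(table$test), table$raw_value)
  table
}

#' Stage-1 cell-wise standardization and outlier removal
#'
#' Within each test x sex x enrollment-group cell, z-scores are computed in a
#' single pass from the full cell (mean and n-1 standard deviation); rows
#' whose absolute z strictly exceeds `k` are removed. Cell statistics are not
#' recomputed after removal. `scope = "child"` removes every row of a child
#' who owns at least one flagged observation (to reproduce child-level
#' exclusion accounting); the default removes only the offending rows.
#'
#' @param table Observation table with `pace_value`, `test`, `sex`, `group`.
#' @param k SD multiple; strict inequality (`|z| = k` is retained).
#' @param scope `"observation"` or `"child"`.
#' @return List with `table` (retained rows, `z1` column added), `removed`
#'   (removed rows with `z1` and `removal_reason`), `n_removed_rows`,
#'   `n_removed_children` (children all of whose removal stems from the
#'   filter under `scope = "child"`, or owners of removed rows otherwise).
#' @export
stage1_filter <- function(table, k = 3, scope = c("observation", "child")) {
  scope <- match.arg(scope)
  stopifnot(all(c("pace_value", "test", "sex", "group") %in% names(table)))
  grp <- interaction(table$test, table$sex, table$group, drop = TRUE)
  mu <- tapply(table$pace_value, grp, mean)
  sdev <- tapply(table$pace_value, grp, sd)
  counts <- tapply(table$pace_value, grp, length)
  bad_cell <- is.na(sdev) | sdev == 0 | counts < 2
  if (any(bad_cell)) {
    stop("degenerate stage-1 cell(s) (fewer than 2 distinct values): ",
         paste(names(which(bad_cell)), collapse = ", "))
  }
  z1 <- (table$pace_value - mu[grp]) / sdev[grp]
  table$z1 <- as.numeric(z1)
  flagged <- abs(table$z1) > k
  if (scope == "child") {
    flagged_children <- unique(table$child_id[flagged])
    drop <- table$child_id %in% flagged_children
  } else {
    drop <- flagged
  }
  removed <- table[drop, , drop = FALSE]
  removed$removal_reason <- ifelse(flagged[drop], "outlier", "outlier_same_child")
  list(
    table = table[!drop, , drop = FALSE],
    removed = removed,
    n_removed_rows = sum(drop),
    n_removed_children = length(unique(table$child_id[drop]))
  )
}

#' Keyage reference statistics for stage-2 standardization
#'
#' Per-test mean and n-1 standard deviation of the pace-transformed keyage
#' scores, pooled over sex by default (sex enters the downstream models as a
#' fixed effect); `by_sex = TRUE` computes test x sex cells instead.
#'
#' @param keyage_table Stage-1-filtered keyage rows with `pace_value`.
#' @param by_sex Compute statistics per test x sex.
#' @return Tibble with `test` (and `sex` if `by_sex`), `mean`, `sd`.
#' @export
reference_stats <- function(keyage_table, by_sex = FALSE) {
  stopifnot("pace_value" %in% names(keyage_table))
  keys <- if (by_sex) c("test", "sex") else "test"
  out <- keyage_table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean = mean(.data$pace_value),
                     sd = sd(.data$pace_value), .groups = "drop")
  if (any(!is.finite(out$sd) | out$sd <= 0)) {
    stop("non-positive reference SD for at least one test")
  }
  out
}

#' Stage-2 standardization against keyage reference statistics
#'
#' `z2 = (pace - ref mean) / ref SD` per test (or test x sex when the
#' reference was computed `by_sex`). Keyage rows standardized against their
#' own statistics have sample mean 0 and SD 1 per test by construction.
#'
#' @param table Pace-transformed, stage-1-filtered table.
#' @param ref Reference statistics from [reference_stats()].
#' @return The table with a `z2` column added.
#' @export
stage2_standardize <- function(table, ref) {
  by_sex <- "sex" %in% names(ref)
  keys <- if (by_sex) c("test", "sex") else "test"
  missing_tests <- setdiff(unique(as.character(table$test)), as.character(ref$test))
  if (length(missing_tests)) {
    stop("test(s) missing from reference statistics: ",
         paste(missing_tests, collapse = ", "))
  }
  idx <- if (by_sex) {
    match(paste(table$test, table$sex), paste(ref$test, ref$sex))
  } else {
    match(as.character(table$test), as.character(ref$test))
  }
  if (anyNA(idx)) stop("reference statistics incomplete for some cells")
  table$z2 <- (table$pace_value - ref$mean[idx]) / ref$sd[idx]
  table
}
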