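#' Decimal age at a reference date
#'
#' Age is the day-count difference between the reference date (usually the
#' test date) and the birthdate, divided by 365.25. No rounding is applied;
#' this decimal age is the model covariate, not the basis of enrollment-group
#' classification (see [classify_enrollment()]).
#'
#' @param reference_date,birthdate `Date` vectors (or strings coercible via
#'   `as.Date`); recycled to a common length.
#' @return Numeric vector of ages in decimal years.
#' @export
age_at <- function(reference_date, birthdate) {
  reference_date <- as.Date(reference_date)
  birthdate <- as.Date(birthdate)
  if (any(!is.na(reference_date) & !is.na(birthdate) & birthdate > reference_date)) {
    stop("birthdate after reference_date")
  }
  as.numeric(reference_date - birthdate) / 365.25
}

# completed years of age at `at`, by calendar month/day comparison
.completed_years <- function(birthdate, at) {
  bl <- as.POSIXlt(birthdate)
  al <- as.POSIXlt(at)
  years <- al$year - bl$year
  before_anniversary <- (al$mon < bl$mon) | (al$mon == bl$mon & al$mday < bl$mday)
  years - as.integer(before_anniversary)
}

#' Classify children into enrollment groups from birthdate and cutoff
#'
#' Enrollment group is a pure function of birthdate and the school-enrollment
#' cutoff date of the assessment year (September 30 by default). Completed
#' years of age on the cutoff date -- computed by exact calendar month/day
#' comparison, not the 365.25-day rule -- determine the label: 7 completed
#' years is younger-than-keyage (`ytk`), 8 is `keyage`, 9 is
#' older-than-keyage (`otk`); 6 or fewer is `excluded_young` and 10 or more
#' `excluded_old`. A child born exactly on the cutoff date has completed the
#' year (e.g. exactly 9y0m is `otk`).
#'
#' @param birthdate `Date` vector (or coercible).
#' @param assessment_year Integer calendar year(s) of the assessment.
#' @param cutoff_month_day Cutoff as `"MM-DD"`; default `"09-30"`.
#' @return Factor with levels `ytk`, `keyage`, `otk`, `excluded_young`,
#'   `excluded_old`.
#' @export
classify_enrollment <- function(birthdate, assessment_year,
                                cutoff_month_day = "09-30") {
  birthdate <- as.Date(birthdate)
  n <- max(length(birthdate), length(assessment_year))
  birthdate <- rep_len(birthdate, n)
  assessment_year <- rep_len(as.integer(assessment_year), n)
  cutoff <- as.Date(paste0(assessment_year, "-", cutoff_month_day))
  if (any(!is.na(birthdate) & birthdate >= cutoff)) {
    stop("birthdate on or after the enrollment cutoff date of the assessment year")
  }
  yrs <- .completed_years(birthdate, cutoff)
  lab <- dplyr::case_when(
    yrs <= 6 ~ "excluded_young",
    yrs == 7 ~ "ytk",
    yrs == 8 ~ "keyage",
    yrs == 9 ~ "otk",
    yrs >= 10 ~ "excluded_old"
  )
  factor(lab, levels = c("ytk", "keyage", "otk", "excluded_young", "excluded_old"))
}

#' Annotate an observation table with enrollment group and decimal age
#'
#' Adds `group` (from [classify_enrollment()], using birthdate and the cutoff
#' of each row's assessment year) and `age_years` (decimal age at the test
#' date) columns.
#'
#' @param table Observation table (see [read_observations()] for the schema).
#' @param cutoff_month_day Cutoff as `"MM-DD"`.
#' @return The table with `group` and `age_years` columns added.
#' @export
annotate_cohort <- function(table, cutoff_month_day = "09-30") {
  table$group <- classify_enrollment(table$birthdate, table$assessment_year,
                                     cutoff_month_day)
  table$age_years <- age_at(table$test_date, table$birthdate)
  table
}

#' Apply age and health exclusions, keeping a ledger
#'
#' Removes children outside the ytk--otk age bands (`excluded_young`,
#' `excluded_old`) and children flagged for adverse health events. Retained
#' rows are never altered (pure filter). Counts are reported both as children
#' and as child-by-test rows; the stage order (age first, then health)
#' mirrors the order in which the exclusions are applied. An outlier stage
#' can be appended later by [append_outlier_stage()] after stage-1 filtering.
#'
#' @param table Annotated observation table (must carry `group`,
#'   `health_exclusion`).
#' @return List with `table` (retained rows) and `ledger` (tibble with
#'   columns `stage`, `children`, `rows`; negative counts are removals).
#' @export
apply_exclusions <- function(table) {
  stopifnot("group" %in% names(table), "health_exclusion" %in% names(table))
  n_child <- function(x) length(unique(x$child_id))
  initial_children <- n_child(table)
  initial_rows <- nrow(table)

  age_out <- table$group %in% c("excluded_young", "excluded_old")
  after_age <- table[!age_out, , drop = FALSE]

  health_out <- after_age$health_exclusion %in% c(1, TRUE)
  after_health <- after_age[!health_out, , drop = FALSE]

  ledger <- tibble::tibble(
    stage = c("initial", "age", "health", "retained"),
    children = c(initial_children,
                 -(initial_children - n_child(after_age)),
                 -(n_child(after_age) - n_child(after_health)),
                 n_child(after_health)),
    rows = c(initial_rows, -sum(age_out), -sum(health_out), nrow(after_health))
  )
  validate_ledger(ledger)
  list(table = after_health, ledger = ledger)
}

#' Append the stage-1 outlier removal to an exclusion ledger
#'
#' @param ledger Ledger from [apply_exclusions()].
#' @param n_children Number of children removed as outliers.
#' @param n_rows Number of rows removed as outliers.
#' @return The ledger with the outlier stage inserted before `retained` and
#'   the retained counts updated; arithmetic is re-validated.
#' @export
append_outlier_stage <- function(ledger, n_children, n_rows) {
  stopifnot(identical(ledger$stage, c("initial", "age", "health", "retained")))
  ret <- ledger[ledger$stage == "retained", ]
  out <- tibble::tibble(stage = "outlier", children = -n_children, rows = -n_rows)
  new_ret <- tibble::tibble(stage = "retained",
                            children = ret$children - n_children,
                            rows = ret$rows - n_rows)
  ledger <- dplyr::bind_rows(ledger[ledger$stage != "retained", ], out, new_ret)
  validate_ledger(ledger)
  ledger
}

#' Check that a ledger's arithmetic reconciles
#'
#' Initial count plus all (negative) removal stages must equal the retained
#' count, for children and for rows.
#'
#' @param ledger A ledger tibble.
#' @return The ledger, invisibly; errors if the arithmetic does not reconcile.
#' @export
validate_ledger <- function(ledger) {
  for (col in c("children", "rows")) {
    x <- ledger[[col]]
    if (sum(x[ledger$stage != "retained"]) != x[ledger$stage == "retained"]) {
      stop("exclusion ledger does not reconcile for ", col)
    }
  }
  invisible(ledger)
}

#' Read / write long-format observation tables
#'
#' The on-disk schema is UTF-8 comma-delimited with one row per child x test:
#' `child_id`, `school_id`, `assessment_year`, `sex` (`f`/`m`), `birthdate`
#' and `test_date` (ISO-8601), `test` (one of the five battery labels),
#' `raw_value`, `health_exclusion` (0/1). `sex` is recoded to the factor
#' levels `girl`/`boy` on read.
#'
#' @param path File path.
#' @return `read_observations()`: a tibble in the internal schema.
#' @export
read_observations <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "school_id", "assessment_year", "sex", "birthdate",
              "test_date", "test", "raw_value", "health_exclusion")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  tibble::tibble(
    child_id = as.character(raw$child_id),
    school_id = as.character(raw$school_id),
    assessment_year = as.integer(raw$assessment_year),
    sex = factor(ifelse(raw$sex %in% c("f", "girl"), "girl", "boy"), levels = .SEXES),
    birthdate = as.Date(raw$birthdate),
    test_date = as.Date(raw$test_date),
    test = factor(raw$test, levels = .TESTS),
    raw_value = as.numeric(raw$raw_value),
    health_exclusion = as.integer(raw$health_exclusion)
  )
}

#' @rdname read_observations
#' @param table Observation table to write.
#' @return `write_observations()`: the input, invisibly.
#' @export
write_observations <- function(table, path) {
  out <- table
  out$sex <- ifelse(as.character(out$sex) == "girl", "f", "m")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(table)
}
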