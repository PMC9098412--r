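#' Add model design columns to an observation table
#'
#' Adds the numeric covariate columns used by all fitness models:
#' * `H1..H4` -- the sequential-difference contrast row for each row's test
#'   ([sdif_contrasts()] over the battery order);
#' * `T_<test>` -- per-test indicator columns (used for per-test variance
#'   components and nested parameterizations);
#' * `ageL`, `ageQ` -- decimal age centered at `age_center` (default 8.5
#'   years, i.e. 8 years 6 months) and its square;
#' * `sexc` -- sex coded girl = -1/2, boy = +1/2, so a sex coefficient is the
#'   boys-minus-girls difference.
#'
#' @param table Observation table with `test`, `age_years`, `sex`.
#' @param age_center Centering origin for age, decimal years.
#' @return The table with design columns added (attribute `age_center` set).
#' @export
add_design_columns <- function(table, age_center = 8.5) {
  test <- factor(as.character(table$test), levels = .TESTS)
  if (anyNA(test)) stop("unknown test label in table")
  C <- sdif_contrasts(5)
  H <- C[as.integer(test), , drop = FALSE]
  for (j in 1:4) table[[paste0("H", j)]] <- unname(H[, j])
  for (tt in .TESTS) table[[paste0("T_", tt)]] <- as.numeric(test == tt)
  table$ageL <- table$age_years - age_center
  table$ageQ <- table$ageL^2
  table$sexc <- ifelse(as.character(table$sex) == "boy", 0.5, -0.5)
  attr(table, "age_center") <- age_center
  table
}

.T_COLS <- paste0("T_", c("endurance", "coordination", "speed",
                          "power_low", "power_up"))
.H_COLS <- paste0("H", 1:4)

#' Default model specifications for the fitness pipeline
#'
#' Three ready-made [lmm_spec()]s:
#'
#' * `"keyage_reference"` -- the reference model fitted to keyage children's
#'   stage-2 z-scores: fixed effects for the four test contrasts, linear age,
#'   sex, and all their interactions; random structure with correlation
#'   parameters for grand mean + four test contrasts by child, grand mean +
#'   contrasts + sex + age by school, and independent per-test and age
#'   variance components by assessment year. The age term is linear only;
#'   prediction outside the keyage band is a linear extrapolation.
#' * `"otk_delta"` -- delta z-score model for older-than-keyage children:
#'   fixed grand mean, contrasts, linear + quadratic age, sex, and the
#'   age-by-contrast and sex-by-contrast interactions; random per-test
#'   variance components with correlations by child, independent per-test +
#'   age components by school, and an intercept component by year.
#' * `"ytk_delta"` -- the reduced model supported by the much smaller
#'   younger-than-keyage group: fixed grand mean + contrasts only; random
#'   per-test components with correlations by child and independent per-test
#'   components by school.
#'
#' @param kind One of `"keyage_reference"`, `"otk_delta"`, `"ytk_delta"`.
#' @param response Response column (defaults to `"z2"` for the reference and
#'   `"delta"` for the group models).
#' @return An [lmm_spec()].
#' @export
fitness_model_spec <- function(kind = c("keyage_reference", "otk_delta", "ytk_delta"),
                               response = NULL) {
  kind <- match.arg(kind)
  H <- .H_COLS
  Tc <- .T_COLS
  switch(kind,
    keyage_reference = lmm_spec(
      response = response %||% "z2",
      fixed = c(H, "ageL", "sexc",
                paste0(H, ":ageL"), paste0(H, ":sexc"), "ageL:sexc",
                paste0(H, ":ageL:sexc")),
      random = list(
        child = re_block(c("1", H), cp = TRUE),
        school = re_block(c("1", H, "sexc", "ageL"), cp = TRUE),
        year = re_block(c(Tc, "ageL"), cp = FALSE)
      )
    ),
    otk_delta = lmm_spec(
      response = response %||% "delta",
      fixed = c(H, "ageL", "ageQ", "sexc",
                paste0(H, ":ageL"), paste0(H, ":ageQ"), paste0(H, ":sexc")),
      random = list(
        child = re_block(Tc, cp = TRUE),
        school = re_block(c(Tc, "ageL"), cp = FALSE),
        year = re_block("1", cp = FALSE)
      )
    ),
    ytk_delta = lmm_spec(
      response = response %||% "delta",
      fixed = H,
      random = list(
        child = re_block(Tc, cp = TRUE),
        school = re_block(Tc, cp = FALSE)
      )
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nested reparameterization of sex/age effects within tests
#'
#' Rewrites a specification so that the named covariates are estimated
#' separately within each of the five test levels (products with the
#' per-test indicator columns) instead of as main effects plus
#' contrast interactions. On a saturated span the fitted values of the two
#' parameterizations coincide; the nested form reports directly
#' interpretable per-test effects (e.g. the sex difference within each
#' test).
#'
#' @param spec An [lmm_spec()].
#' @param nest Covariate columns to nest within test (default `sexc` plus
#'   any age terms present in the fixed part).
#' @return The reparameterized [lmm_spec()].
#' @export
nested_spec <- function(spec, nest = NULL) {
  if (is.null(nest)) {
    nest <- intersect(c("sexc", "ageL", "ageQ"), spec$fixed)
  }
  keep <- spec$fixed[!vapply(spec$fixed, function(tm) {
    any(vapply(nest, function(v) v %in% strsplit(tm, ":", fixed = TRUE)[[1]],
               logical(1)))
  }, logical(1))]
  nested_terms <- unlist(lapply(nest, function(v) paste0(.T_COLS, ":", v)))
  lmm_spec(spec$response, fixed = c(keep, nested_terms), random = spec$random,
           intercept = spec$intercept)
}

#' Build the design bundle for a fitness model
#'
#' Adds design columns, validates the fixed design (errors on rank
#' deficiency, listing aliased columns) and returns everything [fit_lmm()]
#' needs.
#'
#' @param table Observation table with `test`, `age_years`, `sex`, grouping
#'   columns, and the response.
#' @param spec An [lmm_spec()].
#' @param age_center Centering origin for the age polynomial.
#' @return List with `data` (augmented table), `spec`, `X` (fixed design
#'   matrix) and `formula`.
#' @export
build_design <- function(table, spec, age_center = 8.5) {
  data <- add_design_columns(table, age_center = age_center)
  X <- fixed_design(data, spec)
  list(data = data, spec = spec, X = X, formula = lmm_formula(spec))
}
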