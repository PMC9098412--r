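#' Fit the keyage reference model
#'
#' Fits the reference linear mixed model to keyage children's stage-2
#' z-scores: fixed effects for the four test contrasts, linear age
#' (centered), sex and all their interactions; correlated random effects for
#' grand mean + test contrasts by child and for grand mean + contrasts + sex
#' + age by school; independent per-test and age variance components by
#' assessment year. The fitted model, the reference statistics used for
#' stage-2 standardization, and the centering origin together form the
#' reference against which non-keyage children are predicted.
#'
#' @param keyage_table Keyage rows with `z2` (see [stage2_standardize()]),
#'   `age_years`, `sex`, `school_id`, `assessment_year`.
#' @param ref The [reference_stats()] used to compute `z2`.
#' @param age_center Centering origin, decimal years.
#' @param spec Optional [lmm_spec()] override (defaults to the
#'   `"keyage_reference"` structure of [fitness_model_spec()]).
#' @param start,control Passed to [fit_lmm()].
#' @return Object of class `keyage_reference`: list with `fit`
#'   (an `enrollfit_lmm`), `ref`, `age_center`.
#' @export
fit_keyage_reference <- function(keyage_table, ref, age_center = 8.5,
                                 spec = NULL, start = NULL, control = NULL) {
  stopifnot("z2" %in% names(keyage_table))
  if (length(unique(keyage_table$school_id)) < 2 ||
      length(unique(keyage_table$assessment_year)) < 2) {
    stop("need at least 2 schools and 2 assessment years")
  }
  spec <- spec %||% fitness_model_spec("keyage_reference")
  des <- build_design(.as_model_frame(keyage_table), spec, age_center)
  fit <- fit_lmm(des$data, spec, start = start, control = control)
  structure(list(fit = fit, ref = ref, age_center = age_center),
            class = "keyage_reference")
}

# standard grouping-column names used in model formulas
.as_model_frame <- function(table) {
  table$child <- as.character(table$child_id)
  table$school <- as.character(table$school_id)
  table$year <- as.character(table$assessment_year)
  table
}

#' Predict age-expected performance from the keyage reference
#'
#' The prediction for a (typically non-keyage) child x test row is the fixed
#' part of the reference model -- extrapolated linearly in age beyond the
#' keyage band -- plus the conditional modes (BLUPs) of school and
#' assessment year when those levels appeared in the keyage fit. Child
#' effects contribute zero (the children are new to the model). Setting
#' `re_include = character()` gives a fixed-part-only prediction for
#' sensitivity analysis.
#'
#' @param reference A `keyage_reference`.
#' @param table Rows with `test`, `age_years`, `sex`, `school_id`,
#'   `assessment_year`.
#' @param re_include Grouping factors whose conditional modes enter the
#'   prediction.
#' @return Numeric vector of predicted z-scores.
#' @export
predict_expected <- function(reference, table,
                             re_include = c("school", "year")) {
  stopifnot(inherits(reference, "keyage_reference"))
  newdata <- add_design_columns(.as_model_frame(table),
                                age_center = reference$age_center)
  predict(reference$fit, newdata = newdata, re_include = re_include)
}

#' Delta z-scores: observed minus predicted
#'
#' @param table Observed rows with `z2` (and identifying columns).
#' @param predicted Predicted z-scores, row-aligned with `table`.
#' @return Tibble of delta records: identifying columns, `observed`
#'   (`z2`), `predicted`, and `delta = observed - predicted`.
#' @export
compute_deltas <- function(table, predicted) {
  if (length(predicted) != nrow(table)) {
    stop("predictions are not row-aligned with the observed table")
  }
  out <- table
  out$observed <- table$z2
  out$predicted <- as.numeric(predicted)
  out$delta <- out$observed - out$predicted
  out
}

#' Fit the delta model for one enrollment group
#'
#' Models the delta z-scores of OTK or YTK children with the group's default
#' specification (see [fitness_model_spec()]) or a supplied override. For
#' OTK: grand mean, test contrasts, linear + quadratic age, sex, and
#' age-by-contrast and sex-by-contrast interactions, with per-test child
#' components (correlated), per-test + age school components (independent)
#' and a year intercept. For YTK: grand mean + contrasts only, with per-test
#' child (correlated) and school (independent) components.
#'
#' @param deltas Delta records of a single group ([compute_deltas()]).
#' @param group `"otk"` or `"ytk"`.
#' @param spec Optional [lmm_spec()] override.
#' @param age_center Centering origin for the age polynomial.
#' @param start,control Passed to [fit_lmm()].
#' @return An `enrollfit_lmm`.
#' @export
fit_group_model <- function(deltas, group = c("otk", "ytk"), spec = NULL,
                            age_center = 8.5, start = NULL, control = NULL) {
  group <- match.arg(group)
  spec <- spec %||% fitness_model_spec(paste0(group, "_delta"))
  des <- build_design(.as_model_frame(deltas), spec, age_center)
  fit_lmm(des$data, spec, start = start, control = control)
}

#' Post-hoc nested fit: per-test sex (and age) effects
#'
#' Refits a group delta model with sex (and, when present in the fixed part,
#' the age terms) estimated separately within each of the five test levels,
#' instead of as main effects plus contrast interactions. Reports directly
#' interpretable per-test estimates and z-values; on a saturated span the
#' fitted values agree with the interaction parameterization.
#'
#' @param deltas Delta records of a single group.
#' @param group `"otk"` or `"ytk"`.
#' @param spec Optional main-effects [lmm_spec()] to reparameterize
#'   (defaults to the group default).
#' @inheritParams fit_group_model
#' @return An `enrollfit_lmm` whose fixed table contains terms like
#'   `T_<test>:sexc`.
#' @export
posthoc_nested_fit <- function(deltas, group = c("otk", "ytk"), spec = NULL,
                               age_center = 8.5, start = NULL, control = NULL) {
  group <- match.arg(group)
  spec <- nested_spec(spec %||% fitness_model_spec(paste0(group, "_delta")))
  des <- build_design(.as_model_frame(deltas), spec, age_center)
  fit_lmm(des$data, spec, start = start, control = control)
}

#' Parsimonious selection of the random-effect structure
#'
#' Greedy deviance-based walk over a nested lattice of random-effect
#' structures, without ever inspecting fixed-effect estimates. Backward
#' step: each candidate simplification (dropping a variance-component block
#' or switching correlation parameters off) is tested against the current
#' model with [lrt()] at `alpha`; the drop with the largest p-value above
#' `alpha` is accepted and the walk repeats. Forward step: candidate
#' additions are accepted only when the LRT rejects at `alpha` and the
#' enlarged fit is neither singular nor non-converged (overparameterized
#' fits are treated as unsupported by the data). The boundary-chi-square
#' p-values are conservative, which errs on the side of simpler structures.
#'
#' @param deltas Delta records of a single group.
#' @param start_spec Starting [lmm_spec()].
#' @param add_candidates Optional list of [lmm_spec()]s that enlarge the
#'   accepted structure (tested in the forward step).
#' @param alpha Significance level for the deviance comparisons.
#' @param age_center,control Passed to the underlying fits.
#' @return List with `spec` (accepted structure), `fit` (its fit) and
#'   `trace` (tibble of every comparison: move, deviances, df, statistic, p,
#'   decision -- deviance-based quantities only).
#' @export
select_random_structure <- function(deltas, start_spec,
                                    add_candidates = list(),
                                    alpha = 0.05, age_center = 8.5,
                                    control = NULL) {
  des <- build_design(.as_model_frame(deltas), start_spec, age_center)
  data <- des$data
  trace <- list()
  log_row <- function(move, full, nested, test, decision) {
    tibble::tibble(move = move,
                   dev_full = full$deviance, dev_nested = nested$deviance,
                   df = test$df, statistic = test$statistic, p = test$p,
                   decision = decision)
  }

  current_spec <- start_spec
  current <- fit_lmm(data, current_spec, control = control)

  repeat {
    cands <- .drop_moves(current_spec)
    if (!length(cands)) break
    best <- NULL
    for (nm in names(cands)) {
      cand_fit <- try(fit_lmm(data, cands[[nm]], control = control), silent = TRUE)
      if (inherits(cand_fit, "try-error")) next
      test <- lrt(cand_fit, current)
      keep_simpler <- is.na(test$p) || test$p > alpha || !current$converged
      trace[[length(trace) + 1]] <- log_row(
        paste0("drop:", nm), current, cand_fit, test,
        if (keep_simpler) "candidate_drop" else "keep_complex")
      if (keep_simpler && (is.null(best) || test$p > best$p)) {
        best <- list(spec = cands[[nm]], fit = cand_fit, p = test$p, name = nm)
      }
    }
    if (is.null(best)) break
    current_spec <- best$spec
    current <- best$fit
  }

  for (i in seq_along(add_candidates)) {
    cand <- add_candidates[[i]]
    if (!.is_nested(current_spec, cand)) next
    cand_fit <- try(fit_lmm(data, cand, control = control), silent = TRUE)
    if (inherits(cand_fit, "try-error")) next
    test <- lrt(current, cand_fit)
    supported <- !cand_fit$singular && cand_fit$converged &&
      !is.na(test$p) && test$p < alpha
    trace[[length(trace) + 1]] <- log_row(
      paste0("add:", names(add_candidates)[i] %||% as.character(i)),
      cand_fit, current, test,
      if (supported) "accept_addition" else "reject_addition")
    if (supported) {
      current_spec <- cand
      current <- cand_fit
    }
  }

  if (!length(trace)) {
    trace_tbl <- tibble::tibble(move = character(), dev_full = numeric(),
                                dev_nested = numeric(), df = numeric(),
                                statistic = numeric(), p = numeric(),
                                decision = character())
  } else {
    trace_tbl <- dplyr::bind_rows(trace)
  }
  list(spec = current_spec, fit = current, trace = trace_tbl)
}

# candidate one-step simplifications of the random structure:
# per factor, drop one term block, switch CPs off, or drop the factor
.drop_moves <- function(spec) {
  moves <- list()
  for (g in names(spec$random)) {
    b <- spec$random[[g]]
    if (b$cp && length(b$terms) > 1) {
      s <- spec
      s$random[[g]] <- re_block(b$terms, cp = FALSE)
      moves[[paste0(g, ":cp_off")]] <- s
    }
    # drop non-test single terms (age, sex) individually
    droppable <- setdiff(b$terms, c("1", .T_COLS, .H_COLS))
    for (tm in droppable) {
      s <- spec
      s$random[[g]] <- re_block(setdiff(b$terms, tm), cp = b$cp)
      moves[[paste0(g, ":drop_", tm)]] <- s
    }
    # drop the whole factor (only for non-child factors)
    if (g != "child") {
      s <- spec
      s$random[[g]] <- NULL
      moves[[paste0(g, ":drop_factor")]] <- s
    }
  }
  moves
}
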