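#' Random-effect block for a model specification
#'
#' @param terms Character vector of random-effect terms for one grouping
#'   factor: `"1"` for the intercept (grand mean) and/or names of numeric
#'   covariate columns (e.g. sequential-difference contrast columns `H1..H4`,
#'   per-test indicator columns `T_<test>`, `sexc`, `ageL`).
#' @param cp Logical: estimate correlation parameters between the terms
#'   (a full lower-triangular covariance factor) or variance components only
#'   (independent diagonal blocks).
#' @return A list of class `re_block`.
#' @export
re_block <- function(terms, cp = FALSE) {
  stopifnot(is.character(terms), length(terms) >= 1)
  structure(list(terms = unique(terms), cp = isTRUE(cp)), class = "re_block")
}

#' Mixed-model specification
#'
#' A declarative description of a Gaussian linear mixed model: response
#' column, fixed-effect terms (numeric covariate columns and `:` products of
#' them; the intercept is implicit) and, per grouping factor, a [re_block()]
#' listing which terms receive variance components and whether correlation
#' parameters are estimated.
#'
#' @param response Name of the response column.
#' @param fixed Character vector of fixed-effect terms (may be empty for an
#'   intercept-only model).
#' @param random Named list of [re_block()]s, keyed by grouping-factor column.
#' @param intercept Include the fixed intercept (default `TRUE`).
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed = character(), random = list(),
                     intercept = TRUE) {
  stopifnot(is.character(response), length(response) == 1)
  if (length(random)) {
    stopifnot(!is.null(names(random)), all(nzchar(names(random))))
    for (b in random) stopifnot(inherits(b, "re_block"))
  }
  structure(list(response = response, fixed = fixed, random = random,
                 intercept = intercept),
            class = "lmm_spec")
}

# number of covariance parameters implied by the random structure
n_cov_par <- function(spec) {
  sum(vapply(spec$random, function(b) {
    k <- length(b$terms)
    if (b$cp) k * (k + 1) / 2 else k
  }, numeric(1)))
}

# product terms ("a:b:c") are materialized as literal columns so that term
# names and column order are exactly as specified (terms() would otherwise
# re-canonicalize interaction labels)
.materialize_interactions <- function(data, spec) {
  for (tm in spec$fixed[grepl(":", spec$fixed, fixed = TRUE)]) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    miss <- setdiff(parts, names(data))
    if (length(miss)) stop("columns missing from data: ",
                           paste(miss, collapse = ", "))
    data[[tm]] <- Reduce(`*`, data[parts])
  }
  data
}

.fixed_formula_str <- function(spec) {
  quoted <- ifelse(grepl(":", spec$fixed, fixed = TRUE),
                   paste0("`", spec$fixed, "`"), spec$fixed)
  rhs <- c(if (spec$intercept) "1" else "0", quoted)
  paste(spec$response, "~", paste(rhs, collapse = " + "))
}

# one formula fragment per grouping factor (keeps CP-off blocks diagonal)
.random_fragments <- function(spec) {
  frags <- lapply(names(spec$random), function(g) {
    b <- spec$random[[g]]
    if (b$cp) {
      inner <- if ("1" %in% b$terms) {
        paste(c("1", setdiff(b$terms, "1")), collapse = " + ")
      } else {
        paste(c("0", b$terms), collapse = " + ")
      }
      sprintf("(%s | %s)", inner, g)
    } else {
      paste(vapply(b$terms, function(tm) {
        if (tm == "1") sprintf("(1 | %s)", g) else sprintf("(0 + %s | %s)", tm, g)
      }, character(1)), collapse = " + ")
    }
  })
  stats::setNames(frags, names(spec$random))
}

#' Model formula implied by an `lmm_spec`
#'
#' @param spec An [lmm_spec()].
#' @return A formula suitable for `lme4::lmer`.
#' @export
lmm_formula <- function(spec) {
  frags <- .random_fragments(spec)
  txt <- paste(c(.fixed_formula_str(spec), unlist(frags)), collapse = " + ")
  stats::as.formula(txt, env = globalenv())
}

#' Fixed-effect design matrix for a specification
#'
#' Builds the fixed-effect model matrix (intercept first, then terms in the
#' order given) and errors if it is rank deficient, listing the aliased
#' columns.
#'
#' @param data Data frame with all referenced columns.
#' @param spec An [lmm_spec()].
#' @return The model matrix.
#' @export
fixed_design <- function(data, spec) {
  data <- .materialize_interactions(as.data.frame(data), spec)
  f <- stats::as.formula(paste("~", sub(".*~", "", .fixed_formula_str(spec))))
  X <- model.matrix(f, data = data)
  colnames(X) <- sub("^`(.*)`$", "\\1", colnames(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient fixed design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Fit a linear mixed model by REML
#'
#' Fits the model described by an [lmm_spec()] with `lme4::lmer`: profiled
#' REML over the relative covariance factors of the (possibly crossed)
#' grouping factors, with fixed effects and the residual variance profiled
#' out. Boundary estimates (zero variances, singular covariance factors) are
#' admissible and flagged via `singular`. z-values are estimate/SE; no
#' denominator-degrees-of-freedom correction is applied.
#'
#' The identifiability check `check.nobs.vs.nRE` is relaxed because the
#' battery design legitimately estimates a 5-dimensional child term from at
#' most five observations per child (identified through the pooled
#' covariance structure).
#'
#' @param data Data frame.
#' @param spec An [lmm_spec()].
#' @param reml Use REML (default) or ML.
#' @param start Optional start value for the covariance parameter vector
#'   (theta), e.g. from a previous fit of the same structure.
#' @param control An `lme4::lmerControl`; the default uses nloptwrap BOBYQA
#'   without the expensive finite-difference convergence check.
#' @return An object of class `enrollfit_lmm`: list with `fixed` (tibble:
#'   term, estimate, se, z, significant), `vc` (tibble: factor, term,
#'   variance, sd), `cp` (tibble: factor, term1, term2, corr), `modes`
#'   (conditional modes per grouping factor), `deviance` (REML criterion),
#'   `n_cov_par`, `singular`, `converged`, `spec`, and the underlying
#'   `merMod` as `fit`.
#' @export
fit_lmm <- function(data, spec, reml = TRUE, start = NULL, control = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  miss <- setdiff(c(spec$response, names(spec$random)), names(data))
  if (length(miss)) stop("columns missing from data: ", paste(miss, collapse = ", "))
  for (g in names(spec$random)) {
    if (length(unique(data[[g]])) < 2) {
      stop("grouping factor '", g, "' has fewer than 2 levels")
    }
  }
  if (!all(is.finite(data[[spec$response]]))) stop("non-finite response values")
  fixed_design(data, spec)  # rank check (errors if deficient)
  data <- .materialize_interactions(as.data.frame(data), spec)

  if (is.null(control)) {
    control <- lme4::lmerControl(
      optimizer = "nloptwrap", calc.derivs = FALSE,
      check.nobs.vs.nRE = "ignore",
      optCtrl = list(xtol_abs = 1e-7, ftol_abs = 1e-7, maxeval = 1e5)
    )
  }
  form <- lmm_formula(spec)
  environment(form) <- environment()
  fit <- if (is.null(start)) {
    lme4::lmer(form, data = data, REML = reml, control = control)
  } else {
    lme4::lmer(form, data = data, REML = reml, control = control,
               start = list(theta = start))
  }
  .wrap_mermod(fit, spec, reml)
}

.wrap_mermod <- function(fit, spec, reml) {
  est <- lme4::fixef(fit)
  se <- sqrt(Matrix::diag(stats::vcov(fit)))
  fixed <- tibble::tibble(
    term = gsub("`", "", names(est), fixed = TRUE),
    estimate = unname(est), se = unname(se),
    z = unname(est / se)
  )
  fixed$significant <- abs(fixed$z) > Z_CRIT

  vc_all <- as.data.frame(lme4::VarCorr(fit))
  vc_all$factor <- sub("\\.\\d+$", "", vc_all$grp)
  is_cp <- !is.na(vc_all$var2)
  vc <- tibble::tibble(
    factor = vc_all$factor[!is_cp],
    term = ifelse(is.na(vc_all$var1[!is_cp]), "1", vc_all$var1[!is_cp]),
    variance = vc_all$vcov[!is_cp],
    sd = vc_all$sdcor[!is_cp]
  )
  cp <- tibble::tibble(
    factor = vc_all$factor[is_cp],
    term1 = vc_all$var1[is_cp],
    term2 = vc_all$var2[is_cp],
    corr = vc_all$sdcor[is_cp]
  )
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4) == 0

  structure(list(
    fixed = fixed, vc = vc, cp = cp,
    modes = lme4::ranef(fit, condVar = FALSE),
    deviance = if (reml) lme4::REMLcrit(fit) else stats::deviance(fit),
    reml = reml,
    n_cov_par = n_cov_par(spec),
    theta = lme4::getME(fit, "theta"),
    sigma2 = stats::sigma(fit)^2,
    singular = lme4::isSingular(fit),
    converged = conv,
    n_obs = stats::nobs(fit),
    spec = spec,
    fit = fit
  ), class = "enrollfit_lmm")
}

#' @export
#' @method print enrollfit_lmm
#' @rdname fit_lmm
#' @param x,... Print method arguments.
print.enrollfit_lmm <- function(x, ...) {
  cat("Linear mixed model (", if (x$reml) "REML" else "ML", "), ",
      x$n_obs, " observations\n", sep = "")
  cat("deviance:", format(x$deviance, digits = 8),
      " covariance parameters:", x$n_cov_par,
      if (x$singular) " [singular fit]" else "", "\n\n")
  cat("Fixed effects (z = estimate/SE, * = |z| > 2):\n")
  fx <- x$fixed
  fx$sig <- ifelse(fx$significant, "*", "")
  print(as.data.frame(fx[, c("term", "estimate", "se", "z", "sig")]),
        digits = 3, row.names = FALSE)
  cat("\nVariance components:\n")
  print(as.data.frame(x$vc), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted mixed model
#'
#' Prediction is the fixed part plus the conditional modes (BLUPs) of the
#' grouping factors named in `re_include` for levels observed in the fit;
#' unobserved (new) levels contribute zero. Covariates may extrapolate beyond
#' the fitted range.
#'
#' @param object An `enrollfit_lmm`.
#' @param newdata Data frame with all covariate and grouping columns.
#' @param re_include Character vector of grouping factors whose conditional
#'   modes enter the prediction; default none (fixed part only).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.enrollfit_lmm <- function(object, newdata,
                                  re_include = character(), ...) {
  spec <- object$spec
  unknown <- setdiff(re_include, names(spec$random))
  if (length(unknown)) stop("not grouping factors of the fit: ",
                            paste(unknown, collapse = ", "))
  re_form <- if (length(re_include) == 0) {
    ~0
  } else {
    frags <- .random_fragments(spec)[re_include]
    stats::as.formula(paste("~", paste(unlist(frags), collapse = " + ")))
  }
  # coerce grouping columns to character so new levels are allowed
  newdata <- .materialize_interactions(as.data.frame(newdata), spec)
  for (g in names(spec$random)) newdata[[g]] <- as.character(newdata[[g]])
  unname(predict(object$fit, newdata = newdata, re.form = re_form,
                 allow.new.levels = TRUE))
}

# is `nested` a sub-structure of `full`? (same response; fixed and random
# terms subsets; cp only where full has cp)
.is_nested <- function(nested, full) {
  if (!identical(nested$response, full$response)) return(FALSE)
  if (!all(nested$fixed %in% full$fixed)) return(FALSE)
  if (nested$intercept && !full$intercept) return(FALSE)
  for (g in names(nested$random)) {
    bn <- nested$random[[g]]; bf <- full$random[[g]]
    if (is.null(bf)) return(FALSE)
    if (!all(bn$terms %in% bf$terms)) return(FALSE)
    if (bn$cp && !bf$cp && length(bn$terms) > 1) return(FALSE)
  }
  TRUE
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' The statistic is the difference of the (REML or ML) deviances, clipped at
#' zero, with degrees of freedom the difference in parameter counts and a
#' chi-square reference. When the smaller model sits on a variance boundary
#' of the larger (a variance component removed), the chi-square p-value is
#' conservative and is flagged as such. REML deviances are only compared for
#' models with identical fixed effects.
#'
#' @param fit_nested,fit_full Fits from [fit_lmm()] on the same rows.
#' @return List with `statistic`, `df`, `p`, `boundary` (logical flag).
#' @export
lrt <- function(fit_nested, fit_full) {
  stopifnot(inherits(fit_nested, "enrollfit_lmm"),
            inherits(fit_full, "enrollfit_lmm"))
  if (fit_nested$n_obs != fit_full$n_obs) stop("fits use different numbers of rows")
  if (fit_nested$reml != fit_full$reml) stop("mixing REML and ML fits")
  if (!.is_nested(fit_nested$spec, fit_full$spec)) stop("specs are not nested")
  same_fixed <- identical(sort(c(fit_nested$spec$fixed,
                                 if (fit_nested$spec$intercept) "1")),
                          sort(c(fit_full$spec$fixed,
                                 if (fit_full$spec$intercept) "1")))
  if (fit_nested$reml && !same_fixed) {
    stop("REML deviances are not comparable across different fixed effects; ",
         "refit with ML")
  }
  df <- fit_full$n_cov_par - fit_nested$n_cov_par
  if (!same_fixed) df <- df + (nrow(fit_full$fixed) - nrow(fit_nested$fixed))
  stat <- max(0, fit_nested$deviance - fit_full$deviance)
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  boundary <- fit_full$n_cov_par > fit_nested$n_cov_par
  list(statistic = stat, df = df, p = p, boundary = boundary)
}
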