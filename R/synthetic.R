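#' Configuration for the synthetic cohort generator
#'
#' Defines the full generative parameterization of a synthetic testing
#' cohort. Defaults emulate the structure of a large statewide third-grade
#' fitness assessment: three enrollment groups split by a September-30
#' cutoff, five tests per child with ~3% missingness, sex- and age-graded
#' latent fitness with linear age trends, school and assessment-year
#' clustering with child-level variance dominating school-level variance,
#' instrument-precision recording, and group-specific delta shifts (an
#' age-polynomial deficit for older-than-keyage children, a constant
#' advantage for younger-than-keyage children, largest on coordination).
#'
#' Effect-type parameters (`age_slope`, `sex_diff`, the delta profiles) and
#' variance components are expressed on the latent z scale of the generator;
#' [ground_truth_standardized()] converts them to the scale of the fitted
#' pipeline (which standardizes by the empirical keyage SD).
#'
#' @param group_sizes Named integer vector `c(keyage=, otk=, ytk=)` of exact
#'   group sizes; ignored when `n_children`/`group_probs` are supplied.
#' @param n_children,group_probs Alternative: total N and probabilities
#'   (named `ytk`, `keyage`, `otk`, summing to 1) for multinomial group
#'   sampling.
#' @param n_schools,years Number of schools; assessment-year calendar years.
#' @param ref_raw Per-test generating mean/SD on the pace scale.
#' @param age_slope,sex_diff Named per-test linear age trend (z/year) and
#'   boys-minus-girls difference (z).
#' @param delta_otk,delta_ytk Named per-test group delta profiles (z) at the
#'   age centering origin.
#' @param otk_age,ytk_age Linear/quadratic age trend of the group delta,
#'   centered at `age_center`.
#' @param child_vc,child_corr Per-test child variance and between-test
#'   correlation.
#' @param school_vc,school_corr,school_age_vc Per-test school variance,
#'   between-test correlation, and school-level age-slope variance.
#' @param year_vc Assessment-year intercept variance.
#' @param resid_vc Residual variance.
#' @param missingness Probability a child x test row is unrecorded.
#' @param health_rate Probability a child carries a health-exclusion flag.
#' @param age_center Centering origin of age trends (decimal years).
#' @param cutoff_month_day Enrollment cutoff (`"MM-DD"`).
#' @param quantize Round raw scores to instrument precision.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(
    group_sizes = c(keyage = 3000, otk = 800, ytk = 100),
    n_children = NULL, group_probs = NULL,
    n_schools = 40, years = 2011:2013,
    ref_raw = tibble::tibble(
      test = .TESTS,
      mean = c(1004, 2.045, 4.51, 125.6, 3.74),
      sd = c(150, 0.29, 0.41, 19.5, 0.68)
    ),
    age_slope = c(endurance = 0.45, coordination = 0.55, speed = 0.50,
                  power_low = 0.45, power_up = 0.55),
    sex_diff = c(endurance = 0.51, coordination = 0.25, speed = 0.32,
                 power_low = 0.39, power_up = 0.74),
    delta_otk = c(endurance = 0.172, coordination = 0.402, speed = 0.377,
                  power_low = 0.406, power_up = 0.384),
    otk_age = c(linear = -1.014, quadratic = 0.357),
    delta_ytk = c(endurance = 0.033, coordination = 0.107, speed = 0.052,
                  power_low = 0.078, power_up = 0.138),
    ytk_age = c(linear = 0, quadratic = 0),
    child_vc = 0.9, child_corr = 0.5,
    school_vc = 0.08, school_corr = 0.5, school_age_vc = 0.01,
    year_vc = 0.03, resid_vc = 0.65,
    missingness = 0.03, health_rate = 0.001,
    age_center = 8.5, cutoff_month_day = "09-30",
    quantize = TRUE) {
  if (!is.null(group_probs)) {
    stopifnot(!is.null(n_children),
              abs(sum(group_probs) - 1) < 1e-8,
              all(group_probs >= 0))
  }
  norm_tests <- function(x) {
    if (!is.null(names(x))) {
      stopifnot(setequal(names(x), .TESTS))
      x <- x[.TESTS]
    } else {
      stopifnot(length(x) == 5)
      names(x) <- .TESTS
    }
    x
  }
  age_slope <- norm_tests(age_slope)
  sex_diff <- norm_tests(sex_diff)
  delta_otk <- norm_tests(delta_otk)
  delta_ytk <- norm_tests(delta_ytk)
  ref_raw <- ref_raw[match(.TESTS, ref_raw$test), , drop = FALSE]
  stopifnot(all(ref_raw$sd > 0), child_vc >= 0, school_vc >= 0,
            year_vc >= 0, resid_vc >= 0,
            child_corr > -1 / 4, child_corr <= 1,  # 5x5 equicorrelation PSD
            school_corr > -1 / 4, school_corr <= 1,
            missingness >= 0, missingness < 1)
  structure(as.list(environment()), class = "synth_config")
}

# equicorrelated covariance matrix
.equicov <- function(k, v, rho) v * ((1 - rho) * diag(k) + rho * matrix(1, k, k))

.rmvn <- function(n, Sigma) {
  # eigen square root: tolerates positive semidefinite (boundary) inputs
  e <- eigen(Sigma, symmetric = TRUE)
  if (any(e$values < -1e-10)) stop("covariance input is not positive semidefinite")
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncol(Sigma))
  matrix(rnorm(n * ncol(Sigma)), n) %*% t(L)
}

# uniform birthdate giving `target` completed years at the cutoff
.sample_birthdates <- function(n, year, target_years, cutoff_month_day) {
  cutoff <- as.Date(paste0(year, "-", cutoff_month_day))
  upper <- seq(cutoff, by = paste0("-", target_years, " years"), length.out = 2)[2]
  lower <- seq(cutoff, by = paste0("-", target_years + 1, " years"), length.out = 2)[2] + 1
  lower + sample.int(as.integer(upper - lower) + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic testing cohort with known ground truth
#'
#' Samples schools, assessment years and children (birthdates by enrollment
#' group, uniform within the band implied by the cutoff), builds the latent
#' z-score for every child x test as fixed age/sex/test structure + group
#' delta profile + child/school/year random effects + residual, converts the
#' latent score to raw instrument units through the generating reference
#' statistics and the inverse pace transformation, quantizes to instrument
#' precision, and drops rows at the missingness rate. One root seed with
#' per-stage sub-streams makes the draw fully reproducible, and changing the
#' number of children does not perturb the school or year draws.
#'
#' @param config A [synth_config()].
#' @param seed Integer root seed.
#' @return List with `table` (observation tibble in the [read_observations()]
#'   schema) and `truth` (class `synth_truth`: the config, realized random
#'   effects, per-child metadata, and the latent z of every generated row,
#'   including rows later dropped as missing).
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1, 6)

  n_years <- length(config$years)
  # --- schools ---
  set.seed(stage_seed[1])
  school_ids <- sprintf("S%03d", seq_len(config$n_schools))
  Sig_school <- .equicov(5, config$school_vc, config$school_corr)
  school_re <- .rmvn(config$n_schools, Sig_school)
  colnames(school_re) <- .TESTS
  school_age_re <- rnorm(config$n_schools, 0, sqrt(config$school_age_vc))

  # --- assessment years ---
  set.seed(stage_seed[2])
  year_re <- rnorm(n_years, 0, sqrt(config$year_vc))

  # --- children: group, school, year, sex, birthdate, test date ---
  set.seed(stage_seed[3])
  if (!is.null(config$group_probs)) {
    p <- config$group_probs[c("ytk", "keyage", "otk")]
    glab <- sample(c("ytk", "keyage", "otk"), config$n_children,
                   replace = TRUE, prob = p)
  } else {
    gs <- config$group_sizes
    glab <- rep(names(gs), times = gs)
  }
  n_child <- length(glab)
  child_ids <- sprintf("C%06d", seq_len(n_child))
  school_of <- sample(school_ids, n_child, replace = TRUE)
  year_of <- sample(config$years, n_child, replace = TRUE)
  sex_of <- sample(.SEXES, n_child, replace = TRUE)
  target <- c(ytk = 7L, keyage = 8L, otk = 9L)[glab]
  birthdate <- as.Date(rep(NA_integer_, n_child), origin = "1970-01-01")
  for (y in config$years) {
    for (a in c(7L, 8L, 9L)) {
      idx <- which(year_of == y & target == a)
      if (length(idx)) {
        birthdate[idx] <- .sample_birthdates(length(idx), y, a,
                                             config$cutoff_month_day)
      }
    }
  }
  # tests run mid-September to end of November of the assessment year
  start <- as.Date(paste0(year_of, "-09-15"))
  test_date <- start + sample.int(77L, n_child, replace = TRUE) - 1L
  health <- as.integer(runif(n_child) < config$health_rate)

  # --- child random effects ---
  set.seed(stage_seed[4])
  Sig_child <- .equicov(5, config$child_vc, config$child_corr)
  child_re <- .rmvn(n_child, Sig_child)
  colnames(child_re) <- .TESTS

  # --- assemble rows ---
  ci <- rep(seq_len(n_child), each = 5)
  ti <- rep(seq_len(5), times = n_child)
  age <- as.numeric(test_date - birthdate)[ci] / 365.25
  ageL <- age - config$age_center
  sexc <- ifelse(sex_of == "boy", 0.5, -0.5)[ci]
  yi <- match(year_of, config$years)[ci]
  si <- match(school_of, school_ids)[ci]

  delta <- numeric(length(ci))
  is_otk <- glab[ci] == "otk"
  is_ytk <- glab[ci] == "ytk"
  delta[is_otk] <- config$delta_otk[ti[is_otk]] +
    config$otk_age["linear"] * ageL[is_otk] +
    config$otk_age["quadratic"] * ageL[is_otk]^2
  delta[is_ytk] <- config$delta_ytk[ti[is_ytk]] +
    config$ytk_age["linear"] * ageL[is_ytk] +
    config$ytk_age["quadratic"] * ageL[is_ytk]^2

  set.seed(stage_seed[5])
  resid <- rnorm(length(ci), 0, sqrt(config$resid_vc))
  z <- config$age_slope[ti] * ageL + config$sex_diff[ti] * sexc + delta +
    child_re[cbind(ci, ti)] + school_re[cbind(si, ti)] +
    school_age_re[si] * ageL + year_re[yi] + resid

  ref <- config$ref_raw
  pace <- ref$mean[ti] + ref$sd[ti] * z
  pace <- pmax(pace, 0.05 * ref$mean[ti])  # guard against impossible scores
  raw <- from_pace(.TESTS[ti], pace)
  if (config$quantize) {
    prec <- test_definitions()$precision[ti]
    raw <- round(raw / prec) * prec
  }

  table <- tibble::tibble(
    child_id = child_ids[ci],
    school_id = school_of[ci],
    assessment_year = as.integer(year_of[ci]),
    sex = factor(sex_of[ci], levels = .SEXES),
    birthdate = birthdate[ci],
    test_date = test_date[ci],
    test = factor(.TESTS[ti], levels = .TESTS),
    raw_value = as.numeric(raw),
    health_exclusion = health[ci]
  )

  set.seed(stage_seed[6])
  keep <- runif(nrow(table)) >= config$missingness
  truth <- structure(list(
    config = config,
    school_effects = tibble::tibble(school_id = school_ids,
                                    age_slope = school_age_re) |>
      dplyr::bind_cols(tibble::as_tibble(school_re)),
    year_effects = tibble::tibble(year = config$years, intercept = year_re),
    child_effects = tibble::tibble(child_id = child_ids) |>
      dplyr::bind_cols(tibble::as_tibble(child_re)),
    children = tibble::tibble(child_id = child_ids, group = glab,
                              school_id = school_of, assessment_year = year_of,
                              sex = sex_of, birthdate = birthdate,
                              test_date = test_date),
    rows = tibble::tibble(child_id = child_ids[ci], test = .TESTS[ti],
                          latent_z = as.numeric(z), true_delta = delta,
                          observed = keep),
    seed = seed
  ), class = "synth_truth")
  list(table = table[keep, , drop = FALSE], truth = truth)
}

#' Ground truth on the scale of the fitted pipeline
#'
#' The pipeline standardizes pace scores by the empirical keyage mean and SD
#' (stage 2), so parameters configured on the generator's latent z scale
#' appear in fitted models multiplied by the per-test factor
#' `f = generating SD / empirical keyage SD`. This helper performs that exact
#' conversion given the reference statistics actually used.
#'
#' @param truth A `synth_truth` from [generate_cohort()].
#' @param ref Reference statistics ([reference_stats()]) used by the fit.
#' @return List with `per_test` (tibble: test, scale factor, standardized age
#'   slope, sex difference, delta profiles, child/school/residual variances)
#'   and `otk_age`/`ytk_age` (standardized shared age polynomials, averaged
#'   over the per-test factors).
#' @export
ground_truth_standardized <- function(truth, ref) {
  cfg <- truth$config
  i <- match(.TESTS, as.character(ref$test))
  if (anyNA(i)) stop("reference statistics must cover all five tests")
  f <- cfg$ref_raw$sd / ref$sd[i]
  per_test <- tibble::tibble(
    test = .TESTS,
    scale = f,
    age_slope = unname(cfg$age_slope) * f,
    sex_diff = unname(cfg$sex_diff) * f,
    delta_otk = unname(cfg$delta_otk) * f,
    delta_ytk = unname(cfg$delta_ytk) * f,
    child_vc = cfg$child_vc * f^2,
    school_vc = cfg$school_vc * f^2,
    resid_vc = cfg$resid_vc * f^2
  )
  list(
    per_test = per_test,
    otk_age = cfg$otk_age * mean(f),
    ytk_age = cfg$ytk_age * mean(f),
    otk_grand_mean = mean(per_test$delta_otk),
    ytk_grand_mean = mean(per_test$delta_ytk),
    otk_h1 = per_test$delta_otk[2] - per_test$delta_otk[1],
    ytk_h1 = per_test$delta_ytk[2] - per_test$delta_ytk[1]
  )
}

#' Plant gross outliers in an observation table
#'
#' Replaces a random subset of scores with values at +/- `magnitude` cell
#' SDs from the cell mean (cells are test x sex x enrollment group on the
#' pace scale), to exercise the stage-1 outlier filter.
#'
#' @param table Annotated observation table (with `group`).
#' @param rate Fraction of rows to contaminate, in `[0, 1)`.
#' @param magnitude Offset in cell SDs (> 3 to be detectable at `k = 3`).
#' @param seed Integer seed.
#' @return List with `table` (contaminated) and `planted` (tibble of
#'   `child_id`, `test` of the planted rows).
#' @export
inject_outliers <- function(table, rate, magnitude, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) {
    return(list(table = table, planted = tibble::tibble(child_id = character(),
                                                        test = character())))
  }
  set.seed(seed)
  pace <- to_pace(as.character(table$test), table$raw_value)
  grp <- interaction(table$test, table$sex, table$group, drop = TRUE)
  mu <- tapply(pace, grp, mean)[grp]
  sdev <- tapply(pace, grp, sd)[grp]
  n_plant <- round(rate * nrow(table))
  idx <- sample.int(nrow(table), n_plant)
  sign <- sample(c(-1, 1), n_plant, replace = TRUE)
  new_pace <- as.numeric(mu[idx] + sign * magnitude * sdev[idx])
  new_pace <- pmax(new_pace, 1e-3)
  raw <- from_pace(as.character(table$test[idx]), new_pace)
  prec <- test_definitions()$precision[match(table$test[idx], .TESTS)]
  table$raw_value[idx] <- round(raw / prec) * prec
  list(table = table,
       planted = tibble::tibble(child_id = table$child_id[idx],
                                test = as.character(table$test[idx])))
}

#' Synthesize a cohort stream with exact exclusion-category counts
#'
#' Builds an observation stream containing exactly the requested numbers of
#' retained children, stage-1 outlier children, health-flagged children and
#' out-of-age-band children, for exercising the exclusion ledger
#' end to end with known bookkeeping. Clean pace scores lie in a narrow
#' uniform band while each planted outlier child carries one extreme
#' endurance score, so the stage-1 filter (child scope, `k = 3`) flags
#' exactly the planted children: the planted standardized residuals exceed 5
#' while clean ones stay far below 1, for any mix of counts.
#'
#' @param n_clean Children that should survive every exclusion stage.
#' @param n_outlier Children flagged by the stage-1 filter (one extreme
#'   score each).
#' @param n_health Children carrying the health-exclusion flag.
#' @param n_age_excluded Children born outside the ytk--otk bands (too old
#'   for `"otk"` streams, too young for `"ytk"`).
#' @param group Enrollment band of the stream (`"otk"` or `"ytk"`).
#' @param year Assessment year.
#' @param seed Integer seed.
#' @return An observation tibble in the [read_observations()] schema.
#' @export
synthesize_exclusion_stream <- function(n_clean, n_outlier = 0, n_health = 0,
                                        n_age_excluded = 0,
                                        group = c("otk", "ytk"),
                                        year = 2011, seed = 1) {
  group <- match.arg(group)
  set.seed(seed)
  target <- if (group == "otk") 9L else 7L
  excl_target <- if (group == "otk") 10L else 6L
  n_child <- n_clean + n_outlier + n_health + n_age_excluded
  kind <- rep(c("clean", "outlier", "health", "age"),
              c(n_clean, n_outlier, n_health, n_age_excluded))
  cutoff <- as.Date(sprintf("%d-09-30", year))
  band_dates <- function(a, n) {
    upper <- seq(cutoff, by = sprintf("-%d years", a), length.out = 2)[2]
    lower <- seq(cutoff, by = sprintf("-%d years", a + 1),
                 length.out = 2)[2] + 1
    lower + sample.int(as.integer(upper - lower) + 1L, n, TRUE) - 1L
  }
  birth <- as.Date(rep(NA_integer_, n_child), origin = "1970-01-01")
  in_band <- kind != "age"
  birth[in_band] <- band_dates(target, sum(in_band))
  if (any(!in_band)) birth[!in_band] <- band_dates(excl_target, sum(!in_band))

  base_pace <- c(1000, 2, 4.5, 125, 3.7)
  spread <- base_pace / 10
  ci <- rep(seq_len(n_child), each = 5)
  ti <- rep(1:5, n_child)
  pace <- base_pace[ti] + runif(n_child * 5, -1, 1) * spread[ti]
  plant <- which(kind[ci] == "outlier" & ti == 1)
  pace[plant] <- base_pace[1] + 60 * spread[1]

  tibble::tibble(
    child_id = sprintf("%s%06d", toupper(group), ci),
    school_id = sprintf("S%03d", (ci %% 50) + 1),
    assessment_year = year,
    sex = factor(ifelse(ci %% 2 == 0, "girl", "boy"), c("girl", "boy")),
    birthdate = birth[ci],
    test_date = as.Date(sprintf("%d-10-15", year)),
    test = factor(.TESTS[ti], .TESTS),
    raw_value = from_pace(.TESTS[ti], pace),
    health_exclusion = as.integer(kind[ci] == "health")
  )
}
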