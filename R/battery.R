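#' The five-test fitness battery
#'
#' Canonical test labels, in the battery order used for sequential-difference
#' contrasts: cardiorespiratory endurance (6-min run), coordination (star
#' run), speed (20-m sprint), lower-limb power (standing long jump), and
#' upper-limb power (1-kg ball push).
#'
#' @return Character vector of the five test labels.
#' @export
battery_tests <- function() .TESTS

#' Test definitions: orientation, course length and recording precision
#'
#' The two timed tests (star run, 20-m sprint) are time-valued and carry a
#' course length used for the pace transformation; the remaining three are
#' distance-valued. `precision` is the instrument granularity of the recorded
#' raw score: 9 m for the 6-min run, 0.1 s for the timed tests, 1 cm for the
#' standing long jump and 0.1 m for the ball push.
#'
#' @return A tibble with columns `test`, `orientation`, `course_length`,
#'   `precision`, `raw_unit`, `pace_unit`.
#' @export
test_definitions <- function() {
  tibble::tibble(
    test = .TESTS,
    orientation = c("distance_valued", "time_valued", "time_valued",
                    "distance_valued", "distance_valued"),
    course_length = c(NA, 50.912, 20, NA, NA),
    precision = c(9, 0.1, 0.1, 1, 0.1),
    raw_unit = c("m", "s", "s", "cm", "m"),
    pace_unit = c("m", "m/s", "m/s", "cm", "m")
  )
}

.test_def <- function(test) {
  defs <- test_definitions()
  i <- match(test, defs$test)
  if (anyNA(i)) {
    stop("unknown test label(s): ", paste(unique(test[is.na(i)]), collapse = ", "))
  }
  defs[i, , drop = FALSE]
}

#' Convert raw scores to "higher is better" pace scores
#'
#' Distance-valued tests pass through unchanged; time-valued tests are
#' converted to average pace as course length / time (star run:
#' 50.912 m / time; 20-m sprint: 20 m / time), so that larger values mean
#' better performance on every test.
#'
#' @param test Character vector of test labels (recycled against `raw_value`).
#' @param raw_value Numeric raw scores in instrument units (s, m or cm).
#' @return Numeric vector of pace scores (m/s for timed tests, raw units
#'   otherwise).
#' @seealso [from_pace()] for the inverse used by the synthetic generator.
#' @export
to_pace <- function(test, raw_value) {
  n <- max(length(test), length(raw_value))
  test <- rep_len(test, n)
  raw_value <- rep_len(raw_value, n)
  def <- .test_def(test)
  timed <- def$orientation == "time_valued"
  bad <- timed & !is.na(raw_value) & raw_value <= 0
  if (any(bad)) {
    stop("nonpositive time for time-valued test(s): ",
         paste(unique(test[bad]), collapse = ", "))
  }
  if (any(!timed & !is.na(raw_value) & raw_value < 0)) {
    stop("negative raw score for distance-valued test")
  }
  out <- raw_value
  out[timed] <- def$course_length[timed] / raw_value[timed]
  out
}

#' Inverse of the pace transformation
#'
#' @param test Character vector of test labels.
#' @param pace Numeric pace scores as produced by [to_pace()].
#' @return Raw scores in instrument units.
#' @export
from_pace <- function(test, pace) {
  n <- max(length(test), length(pace))
  test <- rep_len(test, n)
  pace <- rep_len(pace, n)
  def <- .test_def(test)
  timed <- def$orientation == "time_valued"
  if (any(timed & !is.na(pace) & pace <= 0)) stop("nonpositive pace for time-valued test")
  out <- pace
  out[timed] <- def$course_length[timed] / pace[timed]
  out
}

#' Box-Cox diagnostic for a positive-valued score distribution
#'
#' Profiles the Box-Cox log-likelihood of an intercept-only model over a grid
#' of exponents and reports the maximizing exponent. Used to check that a
#' reciprocal-type transformation (lambda near -1) is appropriate for the
#' timed tests; the pipeline itself always applies the pace (reciprocal)
#' transformation to time-valued tests, so this is advisory.
#'
#' @param values Positive numeric vector, length >= 10.
#' @param lambda Grid of exponents to profile over.
#' @return List with `lambda_hat` (profile maximizer), `lambda` (grid) and
#'   `loglik` (profile values).
#' @export
boxcox_diagnostic <- function(values, lambda = seq(-2.5, 2.5, by = 0.01)) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 non-missing values")
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  if (sd(values) == 0) stop("degenerate (constant) input: profile undefined")
  prof <- MASS::boxcox(values ~ 1, lambda = lambda, plotit = FALSE)
  list(
    lambda_hat = prof$x[which.max(prof$y)],
    lambda = prof$x,
    loglik = prof$y
  )
}
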