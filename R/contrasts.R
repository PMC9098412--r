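#' Sequential-difference (repeated) contrasts
#'
#' Contrast matrix for an ordered factor with `n_levels` levels in which
#' coefficient `j` of a model fit equals `mean(level j+1) - mean(level j)`.
#' Column `j` takes the value `-(n-j)/n` for rows `i <= j` and `j/n` for rows
#' `i > j`; columns sum to zero and, together with an intercept, the
#' augmented matrix has full rank. Applied to the five-test battery in
#' canonical order this yields the four test contrasts H1 (coordination vs
#' endurance), H2 (speed vs coordination), H3 (power_low vs speed) and H4
#' (power_up vs power_low).
#'
#' @param n_levels Integer >= 2.
#' @param levels Optional level names for the rows (defaults to
#'   [battery_tests()] when `n_levels == 5`).
#' @return A `n_levels x (n_levels - 1)` matrix with columns named
#'   `H1 ... H(n-1)`.
#' @export
sdif_contrasts <- function(n_levels, levels = NULL) {
  if (n_levels < 2) stop("need at least 2 levels")
  m <- MASS::contr.sdif(n_levels)
  m <- unname(as.matrix(m))
  if (is.null(levels) && n_levels == 5) levels <- .TESTS
  dimnames(m) <- list(levels, paste0("H", seq_len(n_levels - 1)))
  m
}
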