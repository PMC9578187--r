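## Tolvaptan treatment effect and discontinuation dynamics. The effect is a
## constant annual absolute reduction in eGFR decline (default 1.20
## mL/min/1.73 m^2 per year), applied uniformly across CKD stages and Mayo
## subclasses. Discontinuation follows annual probabilities for treatment
## years 1-3 (observed trial attrition), year 4 assumed equal to year 3, and
## thereafter discontinuation only at ESRD. The cohort engine models
## discontinuation as an expected-value attenuation of the effect: the
## reduction in year t is the effect times the fraction still on treatment.

#' Treatment specification for the tolvaptan arm
#'
#' @param annual_effect Annual absolute reduction in eGFR decline versus no
#'   treatment, mL/min/1.73 m^2 per year, >= 0 (default 1.20).
#' @param discontinuation_probs Annual discontinuation probabilities for
#'   treatment years 1-3 (the year-4 value is copied from year 3), or an
#'   explicit length-4 vector. Each in `[0, 1]`. After year 4 patients
#'   discontinue only on reaching ESRD.
#' @param enabled Logical; `FALSE` turns the arm into natural history.
#' @return An object of class `treatment_spec` with the expanded length-4
#'   `discontinuation_probs`.
#' @export
#' @examples
#' treatment_spec(1.2, c(0.15, 0.05, 0.03))
treatment_spec <- function(annual_effect = 1.20,
                           discontinuation_probs = c(0, 0, 0),
                           enabled = TRUE) {
  if (!is.numeric(annual_effect) || length(annual_effect) != 1L ||
      annual_effect < 0) {
    stop("annual_effect must be a single number >= 0", call. = FALSE)
  }
  d <- discontinuation_probs
  if (!is.numeric(d) || !length(d) %in% c(3L, 4L)) {
    stop("discontinuation_probs must have length 3 (year 4 copied from ",
         "year 3) or 4", call. = FALSE)
  }
  if (length(d) == 3L) d <- c(d, d[3L])
  if (any(d < 0 | d > 1)) {
    stop("discontinuation probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(annual_effect = annual_effect,
                 discontinuation_probs = unname(d),
                 enabled = isTRUE(enabled)),
            class = "treatment_spec")
}

#' Fraction of a stratum still on treatment in a given cycle
#'
#' The fraction on treatment during cycle `year_index` (0-based; cycle 0 is
#' the first treatment year) is the product of `1 - d_i` over completed
#' treatment years `i <= min(year_index, 4)`; it is constant after year 4
#' because later discontinuation occurs only at ESRD (handled by the
#' trajectory builder). The same fraction applies to every stratum:
#' discontinuation is independent of CKD stage and Mayo subclass.
#'
#' @param year_index Integer cycle index (vector, >= 0).
#' @param spec A [treatment_spec()].
#' @return Fractions in `[0, 1]`.
#' @export
#' @examples
#' on_treatment_fraction(c(0, 3, 6), treatment_spec(1.2, c(0.1, 0.1, 0.1)))
on_treatment_fraction <- function(year_index, spec) {
  if (any(year_index < 0)) stop("year_index must be >= 0", call. = FALSE)
  surv <- cumprod(1 - spec$discontinuation_probs)  # after years 1..4
  vapply(pmin(as.integer(year_index), 4L),
         function(k) if (k == 0L) 1 else surv[k], numeric(1L))
}

#' Per-year effective reduction in eGFR decline
#'
#' Expected per-cycle reduction in decline for a stratum: the annual effect
#' attenuated by the fraction still on treatment, clamped at the magnitude of
#' the natural slope so decline never turns into improvement (a clamp is
#' reported with a warning). Reductions are additionally zeroed from the cycle
#' after the stratum reaches ESRD by [make_trajectory()], which consumes this
#' schedule.
#'
#' @param spec A [treatment_spec()].
#' @param natural_slope Natural-history annual slope (mL/min/1.73 m^2 per
#'   year, negative for decline).
#' @param horizon Number of annual cycles.
#' @return Numeric vector of length `horizon` of per-year reductions (>= 0).
#' @export
#' @examples
#' effective_slope_schedule(treatment_spec(1.2, c(0.1, 0.1, 0.1)),
#'                          natural_slope = -4, horizon = 6)
effective_slope_schedule <- function(spec, natural_slope, horizon) {
  if (horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  if (!spec$enabled) return(numeric(horizon))
  r <- spec$annual_effect * on_treatment_fraction(seq_len(horizon) - 1L, spec)
  cap <- abs(natural_slope)
  if (any(r > cap)) {
    warning(sprintf(paste0("treatment effect (max %.3f) exceeds the natural ",
                           "decline rate (%.3f); reduction clamped so decline ",
                           "does not become improvement"), max(r), cap),
            call. = FALSE)
    r <- pmin(r, cap)
  }
  r
}
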