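#' @keywords internal
"_PACKAGE"

## Health-state vocabulary shared across the package. G5 is ESRD; "dead" is
## the absorbing sixth state of the model.

#' CKD stage and health-state levels
#'
#' `ckd_stages()` returns the five KDIGO eGFR categories used by the model;
#' `health_states()` appends the absorbing `"dead"` state. Severity is totally
#' ordered `G1 < G2 < G3 < G4 < G5 < dead`.
#'
#' @return Character vector of stage / state labels.
#' @export
#' @examples
#' ckd_stages()
#' health_states()
ckd_stages <- function() c("G1", "G2", "G3", "G4", "G5")

#' @rdname ckd_stages
#' @export
health_states <- function() c(ckd_stages(), "dead")

#' Severity rank of a CKD stage or health state
#'
#' @param state Character vector of stage / state labels.
#' @return Integer severity rank, 1 (`G1`) to 6 (`dead`).
#' @export
stage_severity <- function(state) {
  rank <- match(state, health_states())
  if (anyNA(rank)) {
    stop("unknown health state: ",
         paste(unique(state[is.na(rank)]), collapse = ", "), call. = FALSE)
  }
  rank
}

#' Classify eGFR into a KDIGO CKD stage
#'
#' Assigns the G1-G5 eGFR category. Intervals are half-open with the lower
#' bound inclusive: G1 for eGFR >= 90, G2 for [60, 90), G3 for [30, 60)
#' (G3a and G3b are pooled), G4 for [15, 30), and G5 (ESRD) for eGFR < 15.
#'
#' @param egfr Numeric vector of eGFR values (mL/min/1.73 m^2), >= 0.
#' @return Character vector of stages, same length as `egfr`.
#' @export
#' @examples
#' classify_stage(c(105.8, 52.1, 15, 14.999))
classify_stage <- function(egfr) {
  if (!is.numeric(egfr) || anyNA(egfr) || any(!is.finite(egfr))) {
    stop("egfr must be finite and non-missing", call. = FALSE)
  }
  if (any(egfr < 0)) {
    stop("egfr must be non-negative", call. = FALSE)
  }
  c("G5", "G4", "G3", "G2", "G1")[findInterval(egfr, c(15, 30, 60, 90)) + 1L]
}
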