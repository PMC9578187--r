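## State-specific mortality: a general-population period life table (age ->
## annual death probability qx) scaled by CKD-state risk ratios. The default
## ratios come from USRDS all-cause mortality rates in Medicare patients
## (>= 65-66 years of age, applied to all ages as a proxy): CKD G1-G2 1.80,
## G3 2.13, G4-G5 without renal replacement therapy 3.98, dialysis 6.86,
## transplant 2.10. ESRD (G5) blends the last three by an assumed substate
## mix, since the model does not track dialysis/transplant transitions.

#' Validate a period life table
#'
#' A life table maps integer age to annual death probability `qx`. Ages must
#' be contiguous from a minimum <= 18 to a maximum >= 100, each `qx` in
#' `[0, 1]`, and the terminal `qx` equal to 1. An optional `sex` column
#' (`male` / `female`) supports sex-specific tables; validation then applies
#' per sex.
#'
#' @param lt Data.frame with columns `age`, `qx` and optionally `sex`.
#' @return The validated table, classed `life_table`.
#' @export
validate_life_table <- function(lt) {
  if (!is.data.frame(lt) || !all(c("age", "qx") %in% names(lt))) {
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  }
  if (!is.numeric(lt$age) || !is.numeric(lt$qx) || anyNA(lt$age) ||
      anyNA(lt$qx)) {
    stop("life table age and qx must be numeric and non-missing",
         call. = FALSE)
  }
  groups <- if ("sex" %in% names(lt)) {
    if (!all(lt$sex %in% SEX_LEVELS)) {
      stop("life table sex must be 'male' or 'female'", call. = FALSE)
    }
    split(lt, lt$sex)
  } else {
    list(lt)
  }
  for (g in groups) {
    g <- g[order(g$age), ]
    if (any(g$age != round(g$age)) || any(diff(g$age) != 1)) {
      stop("life table ages must be contiguous integers", call. = FALSE)
    }
    if (min(g$age) > 18 || max(g$age) < 100) {
      stop("life table must span at least ages 18 to 100", call. = FALSE)
    }
    if (any(g$qx < 0 | g$qx > 1)) {
      stop("life table qx values must lie in [0, 1]", call. = FALSE)
    }
    if (g$qx[nrow(g)] != 1) {
      stop("terminal-age qx must equal 1", call. = FALSE)
    }
  }
  class(lt) <- unique(c("life_table", class(lt)))
  lt
}

#' Read a life table from CSV
#'
#' Expects columns `age,qx` or `sex,age,qx`.
#'
#' @param path CSV path.
#' @return Validated `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    stop("life table file not found: ", path, call. = FALSE)
  }
  validate_life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a life table to CSV
#' @param lt A validated life table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mortality model: life table plus CKD-state risk ratios
#'
#' @param life_table A validated [life table][validate_life_table].
#' @param rr_g1_g2,rr_g3,rr_g4_g5_no_rrt,rr_dialysis,rr_transplant Risk
#'   ratios (> 0) multiplying general-population qx in the corresponding
#'   state; defaults are the USRDS-derived values 1.80, 2.13, 3.98, 6.86,
#'   2.10.
#' @param esrd_substate_weights Named fractions over `no_rrt`, `dialysis`,
#'   `transplant` summing to 1; the ESRD (G5) risk ratio is their weighted
#'   mean. The mix is an assumption (no published split); the default
#'   `c(no_rrt = 0.05, dialysis = 0.70, transplant = 0.25)` is flagged as such.
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(life_table,
                            rr_g1_g2 = 1.80, rr_g3 = 2.13,
                            rr_g4_g5_no_rrt = 3.98,
                            rr_dialysis = 6.86, rr_transplant = 2.10,
                            esrd_substate_weights = c(no_rrt = 0.05,
                                                      dialysis = 0.70,
                                                      transplant = 0.25)) {
  life_table <- validate_life_table(life_table)
  ratios <- c(rr_g1_g2, rr_g3, rr_g4_g5_no_rrt, rr_dialysis, rr_transplant)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("risk ratios must be positive", call. = FALSE)
  }
  w <- esrd_substate_weights
  if (!all(c("no_rrt", "dialysis", "transplant") %in% names(w))) {
    stop("esrd_substate_weights must name no_rrt, dialysis, transplant",
         call. = FALSE)
  }
  w <- w[c("no_rrt", "dialysis", "transplant")]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("esrd_substate_weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  blend <- sum(w * c(rr_g4_g5_no_rrt, rr_dialysis, rr_transplant))
  if (blend < rr_g4_g5_no_rrt) {
    warning(sprintf(paste0("blended ESRD risk ratio (%.3f) is below the ",
                           "G4/G5 ratio (%.3f); death probability will not ",
                           "be monotone in stage severity"),
                    blend, rr_g4_g5_no_rrt), call. = FALSE)
  }
  structure(list(life_table = life_table, rr_g1_g2 = rr_g1_g2, rr_g3 = rr_g3,
                 rr_g4_g5_no_rrt = rr_g4_g5_no_rrt, rr_dialysis = rr_dialysis,
                 rr_transplant = rr_transplant, esrd_substate_weights = w),
            class = "mortality_model")
}

#' Risk ratio from published mortality rates
#'
#' Quotient of a group's all-cause mortality rate over the reference
#' (CKD-free) rate, both in deaths per 1000 patient-years. The unrounded
#' quotient is returned and used internally; round to 2 decimals for display.
#'
#' @param rate_group,rate_reference Rates in deaths per 1000 patient-years;
#'   `rate_reference` must be > 0.
#' @return Unrounded risk ratio.
#' @export
#' @examples
#' round(risk_ratio_from_rates(82.2, 45.6), 2)   # 1.80
risk_ratio_from_rates <- function(rate_group, rate_reference) {
  if (any(rate_reference <= 0)) {
    stop("rate_reference must be positive", call. = FALSE)
  }
  rate_group / rate_reference
}

#' Risk ratio applied in a health state
#'
#' G1/G2 share one ratio; G3 its own; G4 the no-RRT ratio; G5 (ESRD) the
#' substate-weighted mean of the no-RRT, dialysis and transplant ratios.
#'
#' @param stage A CKD stage `G1`-`G5` (vectorised); `dead` is rejected.
#' @param model A [mortality_model()].
#' @return Risk ratio(s).
#' @export
state_risk_ratio <- function(stage, model) {
  if (any(stage == "dead")) {
    stop("no risk ratio is defined for the dead state", call. = FALSE)
  }
  if (!all(stage %in% ckd_stages())) {
    stop("unknown CKD stage: ",
         paste(setdiff(stage, ckd_stages()), collapse = ", "), call. = FALSE)
  }
  w <- model$esrd_substate_weights
  blend <- sum(w * c(model$rr_g4_g5_no_rrt, model$rr_dialysis,
                     model$rr_transplant))
  unname(c(G1 = model$rr_g1_g2, G2 = model$rr_g1_g2, G3 = model$rr_g3,
           G4 = model$rr_g4_g5_no_rrt, G5 = blend)[stage])
}

## qx lookup with age floored and clamped to the table range.
lookup_qx <- function(age, lt, sex = NULL) {
  tab <- lt
  if ("sex" %in% names(lt)) {
    if (is.null(sex)) {
      stop("life table is sex-specific; supply sex", call. = FALSE)
    }
    tab <- lt[lt$sex == sex, ]
  }
  tab <- tab[order(tab$age), ]
  idx <- pmin(pmax(floor(age), min(tab$age)), max(tab$age)) - min(tab$age) + 1L
  tab$qx[idx]
}

#' Annual death probability by age and health state
#'
#' `min(1, qx(floor(age)) * state_risk_ratio(stage))`; ages beyond the table
#' range are clamped to the terminal row.
#'
#' @param age Age in years (vectorised).
#' @param stage CKD stage `G1`-`G5` (scalar or same length as `age`).
#' @param model A [mortality_model()].
#' @param sex Required when the life table is sex-specific.
#' @return Death probabilities in `[0, 1]`.
#' @export
annual_death_probability <- function(age, stage, model, sex = NULL) {
  pmin(1, lookup_qx(age, model$life_table, sex) * state_risk_ratio(stage, model))
}

#' Life expectancy implied by a life table
#'
#' Remaining life expectancy at `age0` under the model's annual-cycle
#' convention: one full year is lived for each cycle entered alive, and death
#' occurs at cycle end with probability `qx(floor(age))`. This closed-form
#' accounting identity is what the cohort engine must reproduce exactly when
#' all risk ratios are 1 and no stratum progresses.
#'
#' @param lt A validated life table.
#' @param age0 Starting age in years.
#' @param sex Required for sex-specific tables.
#' @param horizon Maximum number of cycles (default: run to extinction).
#' @return Expected remaining life years.
#' @export
life_table_life_expectancy <- function(lt, age0, sex = NULL, horizon = 200L) {
  surv <- 1
  total <- 0
  for (t in seq_len(horizon) - 1L) {
    total <- total + surv
    surv <- surv * (1 - lookup_qx(age0 + t, lt, sex))
    if (surv < 1e-15) break
  }
  total
}
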