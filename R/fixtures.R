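## Synthetic fixtures: a Gompertz-Makeham period life table standing in for a
## national general-population table, and seed-reproducible random cohorts.
## Both are first-class generators so every analysis and test runs offline.

#' Generate a synthetic Gompertz-Makeham life table
#'
#' Annual death probability `qx(age) = min(1, a + c * exp(b * age))`, with the
#' terminal-age qx forced to 1. The default parameters (`a` 2e-4, `b` 0.095,
#' `c` 3e-5) give adult mortality of a realistic order for a contemporary
#' high-income population (for example qx at age 40 of about 0.0015).
#'
#' @param a Makeham age-independent hazard component (>= 0).
#' @param b Gompertz log-slope per year of age (> 0).
#' @param c Gompertz level at age 0 (>= 0).
#' @param age_min,age_max Age range (integer years); must cover 18-100.
#' @return A validated [life table][validate_life_table].
#' @export
#' @examples
#' lt <- generate_life_table_fixture()
#' lt[lt$age %in% c(20, 40, 60, 80), ]
generate_life_table_fixture <- function(a = 2e-4, b = 0.095, c = 3e-5,
                                        age_min = 0L, age_max = 100L) {
  if (a < 0 || c < 0 || b <= 0) {
    stop("require a >= 0, c >= 0, b > 0", call. = FALSE)
  }
  age <- seq.int(age_min, age_max)
  qx <- pmin(1, a + c * exp(b * age))
  if (any(qx[age < 60] >= 1)) {
    stop("parameters give qx = 1 before age 60; implausible life table",
         call. = FALSE)
  }
  qx[length(qx)] <- 1
  validate_life_table(data.frame(age = age, qx = qx))
}

#' Generate a synthetic random cohort
#'
#' Draws seed-reproducible strata satisfying every cohort invariant: unique
#' (sex, subclass, stage) keys, baseline stage derived from the sampled eGFR,
#' positive counts. Useful for property tests and sensitivity work.
#'
#' @param n_strata Number of strata to generate.
#' @param seed Integer seed (required; determinism contract).
#' @param age_range,egfr_range,count_range Sampling ranges. `egfr_range` must
#'   stay above 30 so baseline stages fall in G1-G3.
#' @return A validated cohort.
#' @export
#' @examples
#' generate_synthetic_cohort(4, seed = 1)
generate_synthetic_cohort <- function(n_strata = 6L, seed,
                                      age_range = c(20, 50),
                                      egfr_range = c(30, 110),
                                      count_range = c(10L, 200L)) {
  if (missing(seed) || is.null(seed)) {
    stop("generate_synthetic_cohort requires a seed", call. = FALSE)
  }
  if (egfr_range[1L] < 30 || egfr_range[2L] <= egfr_range[1L]) {
    stop("egfr_range must be increasing and start at >= 30 (stages G1-G3)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- list()
  keys <- character()
  attempts <- 0L
  while (length(rows) < n_strata) {
    attempts <- attempts + 1L
    if (attempts > 200L * n_strata) {
      stop("could not generate ", n_strata, " strata with unique ",
           "(sex, subclass, stage) keys in the requested eGFR range",
           call. = FALSE)
    }
    sex <- sample(SEX_LEVELS, 1L)
    subclass <- sample(MAYO_SUBCLASSES, 1L)
    egfr <- round(stats::runif(1L, egfr_range[1L], egfr_range[2L]), 1L)
    stage <- classify_stage(egfr)
    key <- paste(sex, subclass, stage)
    if (key %in% keys) next
    keys <- c(keys, key)
    rows[[length(rows) + 1L]] <- data.frame(
      sex = sex, mayo_subclass = subclass, ckd_stage = stage,
      count = sample(seq.int(count_range[1L], count_range[2L]), 1L),
      mean_age_years = round(stats::runif(1L, age_range[1L], age_range[2L]), 1L),
      mean_egfr = egfr, stringsAsFactors = FALSE
    )
  }
  validate_cohort(do.call(rbind, rows))
}
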