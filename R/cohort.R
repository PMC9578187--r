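## Cohort construction, validation and CSV I/O. A cohort is a data.frame of
## homogeneous representative strata (sex x Mayo subclass x baseline CKD
## stage), each carrying a patient count and stratum-mean baseline age and
## eGFR. Strata are simulated deterministically and weighted by count.

COHORT_COLUMNS <- c("sex", "mayo_subclass", "ckd_stage", "count",
                    "mean_age_years", "mean_egfr")
SEX_LEVELS <- c("male", "female")
MAYO_SUBCLASSES <- c("1C", "1D", "1E")

#' Base-case cohort of rapidly progressing ADPKD patients
#'
#' Returns the packaged 18-stratum base-case cohort: 1280 rapid progressors
#' (Mayo subclasses 1C, 1D, 1E) beginning in CKD stages G1-G3, split by sex
#' (690 male, 590 female), with stratum-mean baseline age and eGFR. Subclasses
#' 1A/1B and atypical morphology are outside the model's scope.
#'
#' @return A cohort data.frame (class `adpkd_cohort`) with columns `sex`,
#'   `mayo_subclass`, `ckd_stage`, `count`, `mean_age_years`, `mean_egfr`.
#' @export
#' @examples
#' coh <- build_base_cohort()
#' sum(coh$count)                      # 1280
#' tapply(coh$count, coh$ckd_stage, sum)
build_base_cohort <- function() {
  coh <- data.frame(
    sex = rep(c("male", "female"), each = 9L),
    mayo_subclass = rep(c("1C", "1D", "1E"), times = 6L),
    ckd_stage = rep(rep(c("G1", "G2", "G3"), each = 3L), times = 2L),
    count = c(89L, 83L, 50L, 126L, 123L, 69L, 37L, 66L, 47L,
              103L, 80L, 42L, 140L, 106L, 34L, 34L, 34L, 17L),
    mean_age_years = c(37.7, 33.1, 27.0, 41.8, 39.3, 34.8, 44.9, 41.7, 37.9,
                       38.6, 33.8, 26.0, 42.5, 39.1, 33.0, 44.6, 41.7, 35.8),
    mean_egfr = c(105.0, 102.9, 112.4, 74.7, 74.7, 74.0, 52.1, 51.7, 48.5,
                  102.9, 107.3, 109.8, 75.6, 74.4, 76.2, 52.5, 51.2, 52.4),
    stringsAsFactors = FALSE
  )
  validate_cohort(coh)
}

#' Construct a single patient stratum
#'
#' Convenience constructor for toy cohorts and tests. The CKD stage is derived
#' from `egfr` via [classify_stage()].
#'
#' @param sex `"male"` or `"female"`.
#' @param subclass Mayo subclass, one of `"1C"`, `"1D"`, `"1E"`.
#' @param age Baseline age in years (> 0).
#' @param egfr Baseline eGFR (mL/min/1.73 m^2).
#' @param count Positive integer number of patients.
#' @return One-row cohort data.frame.
#' @export
patient_stratum <- function(sex, subclass, age, egfr, count = 1L) {
  validate_cohort(data.frame(
    sex = sex, mayo_subclass = subclass, ckd_stage = classify_stage(egfr),
    count = as.integer(count), mean_age_years = age, mean_egfr = egfr,
    stringsAsFactors = FALSE
  ))
}

#' Validate a cohort data.frame
#'
#' Checks the cohort schema and every stratum invariant: known sex / subclass /
#' stage levels, counts >= 1, baseline age > 0, eGFR consistent with the
#' labelled stage, and no duplicate (sex, subclass, stage) key. Errors name the
#' offending row.
#'
#' @param coh A data.frame with the cohort columns.
#' @return The validated cohort, classed `adpkd_cohort`, invisibly usable
#'   anywhere a plain data.frame is.
#' @export
validate_cohort <- function(coh) {
  if (!is.data.frame(coh)) stop("cohort must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(coh))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  coh <- coh[COHORT_COLUMNS]
  if (!nrow(coh)) stop("cohort has no strata", call. = FALSE)

  row_fail <- function(ok, what) {
    if (any(!ok)) {
      stop(sprintf("cohort row %s: %s", paste(which(!ok), collapse = ", "),
                   what), call. = FALSE)
    }
  }
  for (col in c("count", "mean_age_years", "mean_egfr")) {
    if (!is.numeric(coh[[col]]) || anyNA(coh[[col]])) {
      stop(sprintf("cohort column '%s' must be numeric and non-missing", col),
           call. = FALSE)
    }
  }
  row_fail(coh$sex %in% SEX_LEVELS, "sex must be 'male' or 'female'")
  row_fail(coh$mayo_subclass %in% MAYO_SUBCLASSES,
           "mayo_subclass must be one of 1C, 1D, 1E (1A/1B are not modelled)")
  row_fail(coh$ckd_stage %in% c("G1", "G2", "G3"),
           "baseline ckd_stage must be G1, G2 or G3")
  row_fail(coh$count >= 1 & coh$count == round(coh$count),
           "count must be a positive integer")
  row_fail(coh$mean_age_years > 0, "mean_age_years must be positive")
  row_fail(coh$mean_egfr > 15,
           "mean_egfr must exceed 15 (baseline strata are pre-ESRD)")
  row_fail(classify_stage(coh$mean_egfr) == coh$ckd_stage,
           "ckd_stage inconsistent with mean_egfr under KDIGO thresholds")
  key <- paste(coh$sex, coh$mayo_subclass, coh$ckd_stage)
  row_fail(!duplicated(key), "duplicate (sex, subclass, stage) stratum key")

  coh$count <- as.integer(coh$count)
  class(coh) <- unique(c("adpkd_cohort", class(coh)))
  coh
}

#' Read a cohort from CSV
#'
#' Expects the cohort schema
#' `sex,mayo_subclass,ckd_stage,count,mean_age_years,mean_egfr` (UTF-8, comma
#' separated, decimal point, header required) and applies full validation.
#'
#' @param path Path to a cohort CSV file.
#' @return Validated cohort data.frame.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  coh <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(COHORT_COLUMNS, names(coh))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("count", "mean_age_years", "mean_egfr")) {
    val <- suppressWarnings(as.numeric(coh[[col]]))
    bad <- which(is.na(val) & nzchar(coh[[col]]))
    if (length(bad)) {
      stop(sprintf("cohort row %s: column '%s' is not numeric",
                   paste(bad, collapse = ", "), col), call. = FALSE)
    }
    coh[[col]] <- val
  }
  validate_cohort(coh)
}

#' Write a cohort to CSV
#'
#' @param coh Validated cohort.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(coh, path) {
  coh <- validate_cohort(coh)
  utils::write.csv(as.data.frame(coh)[COHORT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.adpkd_cohort <- function(x, ...) {
  cat(sprintf("ADPKD cohort: %d patients in %d strata (%d male, %d female)\n",
              sum(x$count), nrow(x),
              sum(x$count[x$sex == "male"]),
              sum(x$count[x$sex == "female"])))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
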