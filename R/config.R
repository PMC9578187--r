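## YAML run configuration, schema validation with key paths, the high-level
## two-arm pipeline, and tidy-CSV / JSON result writers.

CONFIG_SECTIONS <- c("seed", "cohort", "coefficients", "equation_modes",
                     "treatment", "mortality", "simulation", "psa", "output")

COEF_KEYS <- c("alpha", "beta_sex", "gamma_age", "delta_egfr", "epsilon",
               "lambda_sex_slope", "mu_age_slope",
               "theta_1C", "theta_1D", "theta_1E",
               "sigma_1C", "sigma_1D", "sigma_1E")

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown key(s) under '%s': %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Default run configuration
#'
#' The builtin base-case cohort, published equation coefficients, default
#' conventions, the tolvaptan treatment arm with a placeholder discontinuation
#' schedule (the trial rates are not published here and should be supplied by
#' the user), default risk ratios with the assumed ESRD substate mix, the
#' synthetic life-table fixture, and a 75-cycle horizon.
#'
#' @param seed Integer seed recorded in outputs and used for any sampling.
#' @return A validated configuration list of class `adpkd_config`.
#' @export
default_run_config <- function(seed = 1L) {
  validate_run_config(list(
    seed = as.integer(seed),
    cohort = "builtin",
    equation_modes = list(sex_indicator = "female_indicator",
                          age_interaction = "baseline_age",
                          anchoring = "observed_baseline"),
    treatment = list(enabled = TRUE, annual_effect = 1.20,
                     discontinuation_probs = c(0.15, 0.05, 0.03)),
    mortality = list(life_table = "fixture",
                     rr_g1_g2 = 1.80, rr_g3 = 2.13, rr_g4_g5_no_rrt = 3.98,
                     rr_dialysis = 6.86, rr_transplant = 2.10,
                     esrd_substate_weights = list(no_rrt = 0.05,
                                                  dialysis = 0.70,
                                                  transplant = 0.25)),
    simulation = list(horizon = 75L),
    output = list(directory = ".", formats = list("csv", "json"))
  ))
}

#' Read and validate a YAML run configuration
#'
#' @param path Path to a YAML file with sections `seed`, `cohort`,
#'   `coefficients`, `equation_modes`, `treatment`, `mortality`, `simulation`,
#'   `psa`, `output`. Unknown keys are rejected with their location.
#' @return A validated `adpkd_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run-configuration list
#'
#' @param cfg A named list following the configuration schema.
#' @return The configuration with defaults filled in, classed `adpkd_config`.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a named list", call. = FALSE)
  reject_unknown(cfg, CONFIG_SECTIONS, "config")

  if (is.null(cfg$cohort)) cfg$cohort <- "builtin"
  if (!is.character(cfg$cohort) || length(cfg$cohort) != 1L) {
    stop("'cohort' must be \"builtin\" or a CSV path", call. = FALSE)
  }

  if (!is.null(cfg$coefficients)) {
    reject_unknown(cfg$coefficients, COEF_KEYS, "coefficients")
    bad <- !vapply(cfg$coefficients, function(v)
      is.numeric(v) && length(v) == 1L && is.finite(v), logical(1L))
    if (any(bad)) {
      stop("non-numeric coefficient override(s): ",
           paste(names(cfg$coefficients)[bad], collapse = ", "), call. = FALSE)
    }
  }

  if (!is.null(cfg$equation_modes)) {
    reject_unknown(cfg$equation_modes,
                   c("sex_indicator", "age_interaction", "anchoring"),
                   "equation_modes")
  }
  cfg$equation_modes <- tryCatch(
    do.call(equation_modes, cfg$equation_modes %||% list()),
    error = function(e) stop("equation_modes: ", conditionMessage(e),
                             call. = FALSE))

  if (!is.null(cfg$treatment)) {
    reject_unknown(cfg$treatment,
                   c("enabled", "annual_effect", "discontinuation_probs"),
                   "treatment")
    cfg$treatment <- tryCatch(
      treatment_spec(
        annual_effect = cfg$treatment$annual_effect %||% 1.20,
        discontinuation_probs =
          unlist(cfg$treatment$discontinuation_probs %||% c(0, 0, 0)),
        enabled = cfg$treatment$enabled %||% TRUE),
      error = function(e) stop("treatment: ", conditionMessage(e),
                               call. = FALSE))
  }

  if (!is.null(cfg$mortality)) {
    reject_unknown(cfg$mortality,
                   c("life_table", "rr_g1_g2", "rr_g3", "rr_g4_g5_no_rrt",
                     "rr_dialysis", "rr_transplant", "esrd_substate_weights"),
                   "mortality")
    w <- cfg$mortality$esrd_substate_weights
    if (!is.null(w)) {
      reject_unknown(w, c("no_rrt", "dialysis", "transplant"),
                     "mortality.esrd_substate_weights")
    }
  }

  if (!is.null(cfg$simulation)) {
    reject_unknown(cfg$simulation, c("horizon", "cycle_length_years"),
                   "simulation")
    if (!is.null(cfg$simulation$cycle_length_years) &&
        cfg$simulation$cycle_length_years != 1) {
      stop("simulation.cycle_length_years is fixed at 1 year", call. = FALSE)
    }
    h <- cfg$simulation$horizon %||% 75L
    if (!is.numeric(h) || h < 1) {
      stop("simulation.horizon must be >= 1", call. = FALSE)
    }
  } else {
    cfg$simulation <- list(horizon = 75L)
  }

  if (!is.null(cfg$psa)) {
    reject_unknown(cfg$psa, c("n_iterations", "sd_annual_effect", "interval"),
                   "psa")
    if (is.null(cfg$seed)) {
      stop("a seed is required whenever the psa section is present",
           call. = FALSE)
    }
  }

  if (!is.null(cfg$output)) {
    reject_unknown(cfg$output, c("directory", "formats"), "output")
    fmts <- unlist(cfg$output$formats %||% list("csv", "json"))
    if (!all(fmts %in% c("csv", "json"))) {
      stop("output.formats must be among: csv, json", call. = FALSE)
    }
  } else {
    cfg$output <- list(directory = ".", formats = list("csv", "json"))
  }

  class(cfg) <- c("adpkd_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_coefficients <- function(cfg) {
  co <- irazabal_coefficients()
  ov <- cfg$coefficients
  if (is.null(ov)) return(co)
  for (nm in names(ov)) {
    if (grepl("^(theta|sigma)_", nm)) {
      part <- sub("_.*$", "", nm)
      co[[part]][[sub("^(theta|sigma)_", "", nm)]] <- ov[[nm]]
    } else {
      co[[nm]] <- ov[[nm]]
    }
  }
  do.call(irazabal_coefficients, co)
}

config_mortality <- function(cfg) {
  m <- cfg$mortality
  if (is.null(m)) m <- list()
  lt_spec <- m$life_table %||% "fixture"
  lt <- if (identical(lt_spec, "fixture")) {
    generate_life_table_fixture()
  } else {
    read_life_table(lt_spec)
  }
  args <- list(life_table = lt)
  for (nm in c("rr_g1_g2", "rr_g3", "rr_g4_g5_no_rrt", "rr_dialysis",
               "rr_transplant")) {
    if (!is.null(m[[nm]])) args[[nm]] <- m[[nm]]
  }
  if (!is.null(m$esrd_substate_weights)) {
    args$esrd_substate_weights <- unlist(m$esrd_substate_weights)
  }
  do.call(mortality_model, args)
}

#' Run the full model from a configuration
#'
#' Builds the cohort, coefficients, mortality model and treatment arm from a
#' validated configuration and runs the requested arm(s); with both arms the
#' comparison is included, and a `psa` section triggers the probabilistic
#' sensitivity analysis.
#'
#' @param config An `adpkd_config` (see [read_run_config()],
#'   [default_run_config()]).
#' @param arm `"both"` (default), `"natural"`, or `"tolvaptan"`.
#' @return An object of class `adpkd_results` with elements `arms` (named
#'   list of `adpkd_arm`), `comparison` (when both arms ran), `psa` (when
#'   configured), `conventions`, and `seed`.
#' @export
run_model <- function(config, arm = c("both", "natural", "tolvaptan")) {
  arm <- match.arg(arm)
  config <- validate_run_config(unclass(config))
  cohort <- if (identical(config$cohort, "builtin")) {
    build_base_cohort()
  } else {
    load_cohort(config$cohort)
  }
  coeffs <- config_coefficients(config)
  modes <- config$equation_modes
  mortality <- config_mortality(config)
  horizon <- as.integer(config$simulation$horizon)
  treatment <- config$treatment %||% treatment_spec()
  if (arm == "tolvaptan" && !treatment$enabled) {
    stop("tolvaptan arm requested but treatment.enabled is false",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  arms <- list()
  if (arm %in% c("both", "natural")) {
    arms$natural <- run_arm(cohort, coeffs, modes, mortality, NULL, horizon)
  }
  if (arm %in% c("both", "tolvaptan")) {
    arms$tolvaptan <- run_arm(cohort, coeffs, modes, mortality, treatment,
                              horizon)
  }
  comparison <- if (length(arms) == 2L) {
    compare_arms(arms$natural, arms$tolvaptan)
  }
  psa <- if (!is.null(config$psa)) {
    pc <- psa_config(n_iterations = config$psa$n_iterations %||% 5000L,
                     seed = config$seed,
                     sd_annual_effect = config$psa$sd_annual_effect,
                     interval = config$psa$interval %||% 0.95)
    run_psa(pc, cohort, coeffs, modes, treatment, mortality, horizon)
  }

  structure(list(arms = arms, comparison = comparison, psa = psa,
                 conventions = unclass(modes), seed = config$seed,
                 config = config),
            class = "adpkd_results")
}

flatten_named <- function(x, prefix) {
  data.frame(scope = paste0(prefix, names(x)), value = as.numeric(x),
             stringsAsFactors = FALSE)
}

#' Tidy data.frame of results
#'
#' One row per `arm`, `scope`, `metric`, `value` — times to ESRD and
#' life-years per arm, plus delays, percent improvements, life-year
#' differences and ESRD-time shares under `arm = "difference"`.
#'
#' @param results An `adpkd_results` object.
#' @return A tidy data.frame.
#' @export
results_table <- function(results) {
  rows <- list()
  add <- function(arm, metric, df) {
    df$arm <- arm
    df$metric <- metric
    rows[[length(rows) + 1L]] <<- df
  }
  for (nm in names(results$arms)) {
    a <- results$arms[[nm]]
    add(nm, "time_to_esrd", rbind(
      data.frame(scope = "overall", value = a$time_to_esrd$overall),
      flatten_named(a$time_to_esrd$by_stage, "stage:"),
      flatten_named(a$time_to_esrd$by_subclass, "subclass:"),
      flatten_named(a$time_to_esrd$by_sex, "sex:")))
    add(nm, "life_years", flatten_named(a$life_years, "state:"))
  }
  cmp <- results$comparison
  if (!is.null(cmp)) {
    add("difference", "delay_of_esrd", rbind(
      data.frame(scope = "overall", value = cmp$delay_of_esrd$overall),
      flatten_named(cmp$delay_of_esrd$by_stage, "stage:"),
      flatten_named(cmp$delay_of_esrd$by_subclass, "subclass:"),
      flatten_named(cmp$delay_of_esrd$by_sex, "sex:")))
    add("difference", "percent_improvement", rbind(
      data.frame(scope = "overall", value = cmp$percent_improvement$overall),
      flatten_named(cmp$percent_improvement$by_stage, "stage:"),
      flatten_named(cmp$percent_improvement$by_subclass, "subclass:"),
      flatten_named(cmp$percent_improvement$by_sex, "sex:")))
    add("difference", "life_years", flatten_named(cmp$life_year_difference,
                                                  "state:"))
    add("difference", "esrd_time_share",
        flatten_named(cmp$esrd_time_share, "group:"))
  }
  if (!is.null(results$psa)) {
    add("difference", "psa_interval",
        data.frame(scope = c("lower", "upper"),
                   value = as.numeric(results$psa$interval)))
  }
  out <- do.call(rbind, rows)
  out[c("arm", "scope", "metric", "value")]
}

#' JSON-ready summary of results
#'
#' Mirrors the headline quantities: time to ESRD per arm (overall and by
#' stage / subclass / sex), delay of ESRD, percent improvement, life-years by
#' state, ESRD-time share, the PSA interval when run, the conventions in
#' force, and the seed.
#'
#' @param results An `adpkd_results` object.
#' @return A nested list suitable for `jsonlite::write_json()`.
#' @export
results_summary <- function(results) {
  as_lists <- function(tt) lapply(tt, function(x)
    if (length(names(x))) as.list(x) else x)
  out <- list(
    seed = results$seed,
    conventions = results$conventions,
    time_to_esrd = lapply(results$arms, function(a) as_lists(a$time_to_esrd)),
    life_years_by_state = lapply(results$arms,
                                 function(a) as.list(a$life_years))
  )
  cmp <- results$comparison
  if (!is.null(cmp)) {
    out$delay_of_esrd <- as_lists(cmp$delay_of_esrd)
    out$percent_improvement <- as_lists(cmp$percent_improvement)
    out$life_years_by_state$difference <- as.list(cmp$life_year_difference)
    out$esrd_time_share <- as.list(cmp$esrd_time_share)
  }
  if (!is.null(results$psa)) {
    out$psa_interval <- as.numeric(results$psa$interval)
  }
  out
}

#' Write model results to disk
#'
#' @param results An `adpkd_results` object.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @param psa_draws Also dump per-draw PSA outcomes as CSV.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(results, dir,
                          formats = c("csv", "json"), psa_draws = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if ("csv" %in% formats) {
    f <- file.path(dir, "results.csv")
    utils::write.csv(results_table(results), f, row.names = FALSE,
                     quote = FALSE)
    written <- c(written, f)
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(results_summary(results), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  if (psa_draws && !is.null(results$psa)) {
    f <- file.path(dir, "psa_draws.csv")
    utils::write.csv(results$psa$draws, f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' @export
print.adpkd_results <- function(x, ...) {
  cat("ADPKD disease-progression model results\n")
  cat(sprintf("  conventions: %s / %s / %s; seed %s\n",
              x$conventions$sex_indicator, x$conventions$age_interaction,
              x$conventions$anchoring, x$seed %||% "none"))
  for (a in x$arms) {
    cat(sprintf("  %s: time to ESRD %.1f years, total life-years %.1f\n",
                a$arm, a$time_to_esrd$overall, a$life_years[["total"]]))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  delay of ESRD: %.1f years (%.0f%%)\n",
                x$comparison$delay_of_esrd$overall,
                x$comparison$percent_improvement$overall))
  }
  if (!is.null(x$psa)) print(x$psa)
  invisible(x)
}
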