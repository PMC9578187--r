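## The annual-cycle cohort engine. Each stratum follows its deterministic
## eGFR trajectory; every cycle the alive fraction accrues one state-year in
## the stage occupied at cycle start, eGFR and stage are then updated, and
## death is applied at cycle end with q(floor(age at cycle start)) times the
## risk ratio of the updated stage. Time to ESRD is read off the
## deterministic trajectory and deliberately ignores mortality, so crossing
## times are reproducible from the cohort and equation alone; mortality
## affects only occupancy and life-years.

weighted_mean_time <- function(times, weights) {
  sum(times * weights) / sum(weights)
}

group_mean <- function(times, weights, group) {
  g <- split(seq_along(times), group)
  vapply(g, function(i) weighted_mean_time(times[i], weights[i]), numeric(1L))
}

#' Run one arm of the cohort model
#'
#' Simulates every stratum of `cohort` over `horizon` annual cycles, with or
#' without treatment and mortality, and aggregates occupancy, life-years by
#' health state, and continuous times to ESRD (count-weighted, overall and by
#' baseline stage, Mayo subclass, and sex).
#'
#' @param cohort A validated cohort (see [build_base_cohort()]).
#' @param coeffs [irazabal_coefficients()].
#' @param modes [equation_modes()].
#' @param mortality A [mortality_model()], or `NULL` to simulate an undying
#'   cohort (useful for trajectory-only analyses and tests).
#' @param treatment A [treatment_spec()], or `NULL` for natural history.
#' @param horizon Number of annual cycles (default 75, enough to extinguish
#'   the base cohort against a life table with terminal age 100).
#' @return An object of class `adpkd_arm`: list with `strata` (per-stratum
#'   slopes, crossing times and life-years), `occupancy` (cycles x 6 states,
#'   cohort fractions), `life_years` (per-patient count-weighted years in
#'   each state plus `total`), `time_to_esrd` (overall and `by_stage`,
#'   `by_subclass`, `by_sex`), `horizon`, and the arm label.
#' @export
#' @examples
#' arm <- run_arm(build_base_cohort(), horizon = 40)
#' arm$time_to_esrd$overall
run_arm <- function(cohort, coeffs = irazabal_coefficients(),
                    modes = equation_modes(), mortality = NULL,
                    treatment = NULL, horizon = 75L) {
  cohort <- validate_cohort(cohort)
  horizon <- as.integer(horizon)
  n_states <- length(health_states())
  occupancy <- matrix(0, nrow = horizon + 1L, ncol = n_states,
                      dimnames = list(NULL, health_states()))
  ly <- matrix(0, nrow = nrow(cohort), ncol = length(ckd_stages()),
               dimnames = list(NULL, ckd_stages()))
  crossing <- numeric(nrow(cohort))
  slopes <- numeric(nrow(cohort))
  total_n <- sum(cohort$count)

  for (i in seq_len(nrow(cohort))) {
    stratum <- cohort[i, ]
    s_nat <- annual_slope(stratum$sex, stratum$mean_age_years,
                          stratum$mayo_subclass, coeffs, modes)
    slopes[i] <- s_nat
    sched <- if (!is.null(treatment) && treatment$enabled) {
      effective_slope_schedule(treatment, s_nat, horizon)
    } else {
      NULL
    }
    traj <- make_trajectory(stratum, coeffs, modes, horizon, sched)
    crossing[i] <- traj$esrd_crossing_time
    sev <- stage_severity(traj$stage)

    surv <- numeric(horizon + 1L)
    surv[1L] <- 1
    if (is.null(mortality)) {
      surv[] <- 1
    } else {
      q <- annual_death_probability(
        stratum$mean_age_years + 0:(horizon - 1L),
        traj$stage[2:(horizon + 1L)], mortality, sex = stratum$sex)
      surv[2:(horizon + 1L)] <- cumprod(1 - q)
    }
    # state-years: one year in the cycle-start stage per cycle entered alive
    for (t in seq_len(horizon)) {
      ly[i, sev[t]] <- ly[i, sev[t]] + surv[t]
    }
    w <- stratum$count / total_n
    for (t in seq_len(horizon + 1L)) {
      occupancy[t, sev[t]] <- occupancy[t, sev[t]] + w * surv[t]
      occupancy[t, n_states] <- occupancy[t, n_states] + w * (1 - surv[t])
    }
    if (!is.null(mortality) && surv[horizon + 1L] > 1e-6) {
      warning(sprintf("stratum %d not extinct at horizon (%.2e alive); ",
                      i, surv[horizon + 1L]),
              "life-years are truncated", call. = FALSE)
    }
  }

  w <- cohort$count
  life_years <- colSums(ly * w) / sum(w)
  strata <- as.data.frame(cohort)
  strata$natural_slope <- slopes
  strata$time_to_esrd <- crossing
  for (k in ckd_stages()) strata[[paste0("ly_", k)]] <- ly[, k]

  structure(list(
    arm = if (!is.null(treatment) && treatment$enabled) "tolvaptan" else "natural",
    strata = strata,
    occupancy = occupancy,
    life_years = c(life_years, total = sum(life_years)),
    time_to_esrd = list(
      overall = weighted_mean_time(crossing, w),
      by_stage = group_mean(crossing, w, cohort$ckd_stage),
      by_subclass = group_mean(crossing, w, cohort$mayo_subclass),
      by_sex = group_mean(crossing, w, cohort$sex)
    ),
    horizon = horizon
  ), class = "adpkd_arm")
}

#' @export
print.adpkd_arm <- function(x, ...) {
  cat(sprintf("ADPKD cohort arm: %s (%d strata, horizon %d years)\n",
              x$arm, nrow(x$strata), x$horizon))
  cat(sprintf("  mean time to ESRD: %.1f years\n", x$time_to_esrd$overall))
  cat("  life-years by state:",
      paste(sprintf("%s %.1f", names(x$life_years), x$life_years),
            collapse = ", "), "\n")
  invisible(x)
}

#' Compare treated and untreated arms
#'
#' Computes the delay of ESRD (treated minus untreated mean time to ESRD),
#' percent improvement (delay / untreated time x 100), life-year differences
#' per state, and the share of the treated arm's pre-ESRD years that would
#' have been spent in ESRD without treatment — overall and by baseline stage,
#' subclass, and sex (the ESRD share by sex-by-subclass groups).
#'
#' @param untreated,treated `adpkd_arm` results from the same cohort and
#'   horizon.
#' @return An object of class `adpkd_comparison`.
#' @export
compare_arms <- function(untreated, treated) {
  key <- function(a) paste(a$strata$sex, a$strata$mayo_subclass,
                           a$strata$ckd_stage, a$strata$count)
  if (!identical(key(untreated), key(treated)) ||
      untreated$horizon != treated$horizon) {
    stop("arms were not run on the same cohort and horizon", call. = FALSE)
  }
  delay <- list(
    overall = treated$time_to_esrd$overall - untreated$time_to_esrd$overall,
    by_stage = treated$time_to_esrd$by_stage - untreated$time_to_esrd$by_stage,
    by_subclass = treated$time_to_esrd$by_subclass -
      untreated$time_to_esrd$by_subclass,
    by_sex = treated$time_to_esrd$by_sex - untreated$time_to_esrd$by_sex
  )
  pct <- list(
    overall = 100 * delay$overall / untreated$time_to_esrd$overall,
    by_stage = 100 * delay$by_stage / untreated$time_to_esrd$by_stage,
    by_subclass = 100 * delay$by_subclass / untreated$time_to_esrd$by_subclass,
    by_sex = 100 * delay$by_sex / untreated$time_to_esrd$by_sex
  )

  # ESRD-time share: of the years a group spends pre-ESRD when treated, the
  # fraction it would have spent in ESRD untreated.
  w <- untreated$strata$count
  t_trt <- treated$strata$time_to_esrd
  t_unt <- untreated$strata$time_to_esrd
  share <- function(idx) {
    sum(w[idx] * pmax(0, t_trt[idx] - t_unt[idx])) / sum(w[idx] * t_trt[idx])
  }
  groups <- split(seq_along(w), paste(untreated$strata$sex,
                                      untreated$strata$mayo_subclass))
  esrd_share <- c(vapply(groups, share, numeric(1L)),
                  overall = share(seq_along(w)))

  structure(list(
    delay_of_esrd = delay,
    percent_improvement = pct,
    life_year_difference = treated$life_years - untreated$life_years,
    esrd_time_share = esrd_share,
    time_to_esrd = list(natural = untreated$time_to_esrd,
                        tolvaptan = treated$time_to_esrd),
    life_years = list(natural = untreated$life_years,
                      tolvaptan = treated$life_years)
  ), class = "adpkd_comparison")
}

#' @export
print.adpkd_comparison <- function(x, ...) {
  cat("Tolvaptan vs natural history\n")
  cat(sprintf("  time to ESRD: %.1f vs %.1f years\n",
              x$time_to_esrd$tolvaptan$overall,
              x$time_to_esrd$natural$overall))
  cat(sprintf("  delay of ESRD: %.1f years (%.0f%% improvement)\n",
              x$delay_of_esrd$overall, x$percent_improvement$overall))
  for (k in names(x$delay_of_esrd$by_stage)) {
    cat(sprintf("    from %s: %.1f years (%.0f%%)\n", k,
                x$delay_of_esrd$by_stage[[k]],
                x$percent_improvement$by_stage[[k]]))
  }
  cat(sprintf("  life-years difference (total): %.1f\n",
              x$life_year_difference[["total"]]))
  invisible(x)
}

#' Patient-level Monte-Carlo simulation of a stratum
#'
#' Individual-sampling counterpart of the cohort accounting, used as an
#' independent oracle. Each simulated patient follows the stratum trajectory;
#' death is sampled each cycle from the state- and age-specific probability.
#' With `sample_discontinuation = TRUE`, each patient's discontinuation year
#' (1-4, or never) is drawn from the treatment spec and the patient follows
#' the trajectory in which the full effect stops at that year; otherwise the
#' expected-value schedule of the cohort engine is used, so cohort and
#' patient-level estimands coincide and differ only by Monte-Carlo error.
#'
#' @param stratum One-row cohort data.frame.
#' @param n Number of simulated patients.
#' @param coeffs,modes,mortality,treatment,horizon As in [run_arm()].
#' @param sample_discontinuation Sample per-patient discontinuation years
#'   instead of applying the expected attenuation.
#' @return List with `life_years` (n x 5 matrix of per-patient years in each
#'   CKD state) and `time_to_esrd` (per-patient crossing times; varies only
#'   when discontinuation is sampled).
#' @export
simulate_patients <- function(stratum, n, coeffs = irazabal_coefficients(),
                              modes = equation_modes(), mortality = NULL,
                              treatment = NULL, horizon = 75L,
                              sample_discontinuation = FALSE) {
  horizon <- as.integer(horizon)
  s_nat <- annual_slope(stratum$sex, stratum$mean_age_years,
                        stratum$mayo_subclass, coeffs, modes)

  make_variant <- function(sched) {
    traj <- make_trajectory(stratum, coeffs, modes, horizon, sched)
    sev <- stage_severity(traj$stage)
    q <- if (is.null(mortality)) {
      numeric(horizon)
    } else {
      annual_death_probability(stratum$mean_age_years + 0:(horizon - 1L),
                               traj$stage[2:(horizon + 1L)], mortality,
                               sex = stratum$sex)
    }
    # cumulative state-years by death cycle: patient dying at end of cycle d
    # lived cycles 0..d
    cum_ly <- apply(vapply(seq_len(horizon),
                           function(t) {
                             v <- numeric(5L)
                             v[sev[t]] <- 1
                             v
                           }, numeric(5L)), 1L, cumsum)
    list(sev = sev, q = q, cum_ly = cum_ly, crossing = traj$esrd_crossing_time)
  }

  treated <- !is.null(treatment) && treatment$enabled
  if (treated && sample_discontinuation) {
    d <- treatment$discontinuation_probs
    stay <- cumprod(1 - d)
    # probability of discontinuing during treatment year k = 1..4, else never
    p_disc <- c(d[1L], stay[1L] * d[2L], stay[2L] * d[3L], stay[3L] * d[4L])
    p <- c(p_disc, 1 - sum(p_disc))
    variants <- lapply(1:5, function(k) {
      sched <- rep(treatment$annual_effect, horizon)
      if (k <= 4L) sched[seq.int(k, horizon)] <- 0  # effect stops with drug
      sched <- pmin(sched, abs(s_nat))
      make_variant(sched)
    })
    assignment <- sample.int(5L, n, replace = TRUE, prob = p)
  } else {
    sched <- if (treated) {
      effective_slope_schedule(treatment, s_nat, horizon)
    } else {
      NULL
    }
    variants <- list(make_variant(sched))
    assignment <- rep(1L, n)
  }

  ly <- matrix(0, nrow = n, ncol = 5L, dimnames = list(NULL, ckd_stages()))
  crossing <- numeric(n)
  for (k in seq_along(variants)) {
    idx <- which(assignment == k)
    if (!length(idx)) next
    v <- variants[[k]]
    crossing[idx] <- v$crossing
    # death cycle: first cycle whose end the patient does not survive
    if (is.null(mortality)) {
      cycles_lived <- rep(horizon, length(idx))
    } else {
      cum_surv <- cumprod(1 - v$q)  # P(alive at start of cycle k), k = 1..horizon
      u <- stats::runif(length(idx))
      # patient enters cycle k alive iff u <= cum_surv[k]; cycle 0 always lived
      cycles_lived <- pmin(horizon, findInterval(-u, -c(1, cum_surv)))
    }
    ly[idx, ] <- v$cum_ly[cycles_lived, , drop = FALSE]
  }
  list(life_years = ly, time_to_esrd = crossing)
}
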