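test_that("annual slope matches the published coefficients", {
  # -0.23 + mu*age + sigma_1C, female adds lambda = 0.19
  expect_equal(annual_slope("male", 44.9, "1C"), -3.758)
  expect_equal(annual_slope("female", 44.9, "1C"), -3.568)

  # with the male-indicator convention the 0.19 lands on males instead
  m_male <- equation_modes(sex_indicator = "male_indicator")
  expect_equal(annual_slope("male", 44.9, "1C", modes = m_male), -3.568)
  expect_equal(annual_slope("female", 44.9, "1C", modes = m_male), -3.758)

  # with age and subclass terms silenced only epsilon survives
  co <- suppressWarnings(irazabal_coefficients(
    mu_age_slope = 0, lambda_sex_slope = 0,
    sigma = c("1C" = 0, "1D" = 0, "1E" = 0)))
  expect_equal(annual_slope("male", 40, "1C", co), -0.23)

  expect_error(annual_slope("male", 0, "1C"), "baseline_age")
  expect_error(annual_slope("male", 40, "1B"), "subclass")
})

test_that("predicted eGFR anchors, declines linearly, and floors at zero", {
  s <- patient_stratum("male", "1C", age = 37.7, egfr = 105.0)

  expect_equal(predicted_egfr(s, 0), 105.0)       # anchor identity
  expect_equal(predicted_egfr(s, 10), 105.0 - 10 * 3.614)  # 68.86

  m_int <- equation_modes(anchoring = "equation_intercept")
  expect_equal(predicted_egfr(s, 0, modes = m_int),
               21.18 - 0.26 * 37.7 + 0.90 * 105.0 - 1.14)  # 104.738

  expect_equal(predicted_egfr(s, 1000), 0)        # floored
  expect_error(predicted_egfr(s, -1), "non-negative")
})

test_that("closed-form time to ESRD matches hand arithmetic in both modes", {
  g3 <- patient_stratum("male", "1C", age = 44.9, egfr = 52.1)
  expect_equal(time_to_esrd(g3), (52.1 - 15) / 3.758, tolerance = 1e-12)

  # a modifier equal to the decline rate flattens the trajectory: never
  expect_identical(time_to_esrd(g3, effective_slope_modifier = 3.758), Inf)

  g1 <- patient_stratum("male", "1C", age = 37.7, egfr = 105.0)
  m_cur <- equation_modes(age_interaction = "current_age")
  # positive root of 0.02 t^2 + 3.614 t - 90 = 0
  expect_equal(time_to_esrd(g1, modes = m_cur),
               (-3.614 + sqrt(3.614^2 + 4 * 0.02 * 90)) / 0.04,
               tolerance = 1e-12)
})

test_that("later Mayo subclasses always reach ESRD sooner", {
  for (sex in c("male", "female")) {
    for (age in c(25, 40, 55)) {
      for (egfr in c(105, 75, 50)) {
        tt <- vapply(c("1C", "1D", "1E"), function(sc)
          time_to_esrd(patient_stratum(sex, sc, age = age, egfr = egfr)),
          numeric(1))
        expect_true(tt[["1C"]] > tt[["1D"]] && tt[["1D"]] > tt[["1E"]])
      }
    }
  }
})

test_that("closed-form crossing agrees with a 1e-4-year grid scan", {
  co <- irazabal_coefficients()
  strata <- list(
    patient_stratum("male", "1C", age = 37.7, egfr = 105.0),
    patient_stratum("female", "1D", age = 39.1, egfr = 74.4),
    patient_stratum("male", "1E", age = 37.9, egfr = 48.5)
  )
  for (ai in c("baseline_age", "current_age")) {
    modes <- equation_modes(age_interaction = ai)
    for (s in strata) {
      for (modifier in c(0, 1.2)) {
        closed <- time_to_esrd(s, co, modes, modifier)
        scanned <- grid_scan_crossing(s, co, modes, modifier)
        expect_lt(abs(closed - scanned), 1e-3)
      }
    }
  }
})

test_that("trajectories never improve in stage and anchor exactly at baseline", {
  set.seed(11)
  coh <- generate_synthetic_cohort(6, seed = 11)
  for (i in seq_len(nrow(coh))) {
    stratum <- coh[i, ]
    sched <- runif(30, 0, 2)  # arbitrary non-negative reduction schedule
    for (ai in c("baseline_age", "current_age")) {
      traj <- suppressWarnings(make_trajectory(
        stratum, modes = equation_modes(age_interaction = ai),
        horizon = 30, schedule = sched))
      expect_equal(traj$egfr[1], stratum$mean_egfr)
      expect_true(all(diff(stage_severity(traj$stage)) >= 0))
      expect_true(all(is.finite(traj$egfr)))
    }
  }
})

test_that("trajectory crossing matches closed forms, including piecewise", {
  # constant zero schedule: first ESRD year is the ceiling of 9.872
  g3 <- patient_stratum("male", "1C", age = 44.9, egfr = 52.1)
  traj <- make_trajectory(g3, horizon = 20)
  expect_equal(traj$esrd_crossing_time, time_to_esrd(g3), tolerance = 1e-12)
  expect_equal(min(traj$times[traj$stage == "G5"]), 10)

  # baseline already below 15: immediate ESRD
  low <- g3; low$mean_egfr <- 12
  traj0 <- make_trajectory(low, horizon = 5)
  expect_equal(traj0$esrd_crossing_time, 0)
  expect_equal(traj0$stage[1], "G5")

  # piecewise schedule (effect 1.2 for 3 years, then none) vs segment algebra
  slope <- annual_slope("male", 44.9, "1C")  # -3.758
  sched <- c(rep(1.2, 3), rep(0, 17))
  traj_pw <- make_trajectory(g3, horizon = 20, schedule = sched)
  egfr_after3 <- 52.1 + 3 * (slope + 1.2)
  oracle <- 3 + (egfr_after3 - 15) / abs(slope)
  expect_equal(traj_pw$esrd_crossing_time, oracle, tolerance = 1e-12)

  expect_error(make_trajectory(g3, horizon = 20, schedule = rep(0, 5)),
               "schedule has length")
})
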