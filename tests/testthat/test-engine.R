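test_that("toy stratum reproduces closed-form crossing and state-years", {
  stratum <- toy_stratum(egfr = 55)
  co <- flat_coeffs(-4)

  unt <- run_arm(stratum, co, horizon = 20)
  expect_equal(unt$time_to_esrd$overall, 10)
  pre_esrd <- sum(unt$life_years[c("G1", "G2", "G3", "G4")])
  expect_equal(pre_esrd, 10)  # cycles 0-9 before ESRD, no deaths

  trt <- run_arm(stratum, co, treatment = treatment_spec(1.2, c(0, 0, 0)),
                 horizon = 40)
  expect_equal(trt$time_to_esrd$overall, 40 / 2.8, tolerance = 1e-12)

  cmp <- compare_arms(run_arm(stratum, co, horizon = 40), trt)
  expect_equal(cmp$delay_of_esrd$overall, 40 / 2.8 - 10, tolerance = 1e-12)
  expect_equal(cmp$percent_improvement$overall,
               100 * (40 / 2.8 - 10) / 10, tolerance = 1e-12)  # 42.857%
})

test_that("occupancy over the six states sums to one at every cycle", {
  coh <- build_base_cohort()
  runs <- list(
    run_arm(coh, horizon = 40),
    run_arm(coh, mortality = mortality_model(fixture_life_table()),
            horizon = 75),
    run_arm(coh, mortality = mortality_model(fixture_life_table()),
            treatment = synthetic_treatment(), horizon = 75)
  )
  for (arm in runs) {
    expect_true(all(abs(rowSums(arm$occupancy) - 1) < 1e-9))
  }
})

test_that("an all-lethal life table kills the cohort after one cycle", {
  lt <- validate_life_table(data.frame(age = 0:100, qx = 1))
  arm <- run_arm(toy_stratum(), flat_coeffs(-4),
                 mortality = mortality_model(lt), horizon = 20)
  expect_equal(arm$life_years[["total"]], 1)  # only cycle 0 is lived
  expect_true(all(abs(rowSums(arm$occupancy) - 1) < 1e-9))
  expect_equal(unname(arm$occupancy[2, "dead"]), 1)
})

test_that("a shared constant slope is recovered exactly from crossing times", {
  coh <- generate_synthetic_cohort(6, seed = 3)
  s <- -3.1
  arm <- run_arm(coh, flat_coeffs(s), horizon = 60)
  expect_equal(arm$strata$time_to_esrd, (coh$mean_egfr - 15) / abs(s),
               tolerance = 1e-12)
})

test_that("delay of ESRD shrinks with later baseline stage in every subclass", {
  coh <- build_base_cohort()
  unt <- run_arm(coh, horizon = 75)
  trt <- run_arm(coh, treatment = synthetic_treatment(), horizon = 75)
  per_stratum_delay <- trt$strata$time_to_esrd - unt$strata$time_to_esrd
  for (sex in c("male", "female")) {
    for (sc in c("1C", "1D", "1E")) {
      idx <- coh$sex == sex & coh$mayo_subclass == sc
      d <- per_stratum_delay[idx][order(coh$ckd_stage[idx])]
      expect_true(all(diff(d) < 0))  # G1 > G2 > G3
    }
  }
})

test_that("a zero-effect treated arm is identical to natural history", {
  coh <- generate_synthetic_cohort(5, seed = 5)
  m <- mortality_model(fixture_life_table())
  unt <- run_arm(coh, mortality = m, horizon = 75)
  trt <- run_arm(coh, mortality = m,
                 treatment = treatment_spec(0, c(0.1, 0.1, 0.1)), horizon = 75)
  cmp <- compare_arms(unt, trt)
  expect_equal(cmp$delay_of_esrd$overall, 0)
  expect_equal(unname(cmp$delay_of_esrd$by_stage),
               rep(0, length(cmp$delay_of_esrd$by_stage)))
  expect_equal(unname(cmp$life_year_difference),
               rep(0, length(cmp$life_year_difference)))
})

test_that("arms from different cohorts refuse to be compared", {
  a <- run_arm(generate_synthetic_cohort(4, seed = 1), horizon = 30)
  b <- run_arm(generate_synthetic_cohort(4, seed = 2), horizon = 30)
  expect_error(compare_arms(a, b), "same cohort")
})

test_that("cohort accounting agrees with a patient-level oracle within 3 SE", {
  set.seed(90210)
  m <- mortality_model(fixture_life_table())
  strata <- list(patient_stratum("male", "1D", age = 40, egfr = 75),
                 patient_stratum("female", "1C", age = 35, egfr = 100))
  for (stratum in strata) {
    for (trt in list(NULL, treatment_spec(1.2, c(0, 0, 0)))) {
      arm <- run_arm(stratum, mortality = m, treatment = trt, horizon = 75)
      sim <- simulate_patients(stratum, n = 25000, mortality = m,
                               treatment = trt, horizon = 75)
      for (state in ckd_stages()) {
        mc_mean <- mean(sim$life_years[, state])
        mc_se <- stats::sd(sim$life_years[, state]) / sqrt(nrow(sim$life_years))
        expect_lt(abs(arm$life_years[[state]] - mc_mean),
                  3 * mc_se + 1e-9)
      }
    }
  }
})

test_that("sampling discontinuation delays ESRD at least as much as the
           expected-effect cohort (Jensen direction)", {
  set.seed(17)
  stratum <- patient_stratum("male", "1C", age = 40, egfr = 90)
  trt <- treatment_spec(1.2, c(0.3, 0.15, 0.1))
  arm <- run_arm(stratum, treatment = trt, horizon = 75)
  sim <- simulate_patients(stratum, n = 4000, treatment = trt, horizon = 75,
                           sample_discontinuation = TRUE)
  expect_gte(mean(sim$time_to_esrd), arm$time_to_esrd$overall - 1e-9)
})
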