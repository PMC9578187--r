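test_that("risk ratios recompute from published mortality rates", {
  # USRDS all-cause mortality per 1000 patient-years over the CKD-free rate
  expect_equal(round(risk_ratio_from_rates(82.2, 45.6), 2), 1.80)
  expect_equal(round(risk_ratio_from_rates(97.2, 45.6), 2), 2.13)
  expect_equal(round(risk_ratio_from_rates(181.6, 45.6), 2), 3.98)
  expect_equal(risk_ratio_from_rates(45.6, 45.6), 1.00)
  expect_error(risk_ratio_from_rates(82.2, 0), "positive")
})

test_that("state risk ratios map stages and blend the ESRD substates", {
  lt <- fixture_life_table()
  m <- mortality_model(lt)
  expect_equal(state_risk_ratio(c("G1", "G2"), m), c(1.80, 1.80))
  expect_equal(state_risk_ratio("G3", m), 2.13)
  expect_equal(state_risk_ratio("G4", m), 3.98)
  expect_equal(state_risk_ratio("G5", m),
               0.05 * 3.98 + 0.70 * 6.86 + 0.25 * 2.10)

  m_dial <- mortality_model(lt, esrd_substate_weights = c(no_rrt = 0,
                                                          dialysis = 1,
                                                          transplant = 0))
  expect_equal(state_risk_ratio("G5", m_dial), 6.86)

  m_even <- suppressWarnings(mortality_model(
    lt, esrd_substate_weights = c(no_rrt = 1, dialysis = 1, transplant = 1) / 3))
  expect_equal(state_risk_ratio("G5", m_even), (3.98 + 6.86 + 2.10) / 3)

  expect_error(state_risk_ratio("dead", m), "dead")
  expect_error(mortality_model(lt, esrd_substate_weights =
                                 c(no_rrt = 0.5, dialysis = 0.6,
                                   transplant = 0.1)), "sum to 1")
  # a transplant-heavy mix makes the ESRD blend lighter than G4: warned
  expect_warning(mortality_model(lt, esrd_substate_weights =
                                   c(no_rrt = 0, dialysis = 0,
                                     transplant = 1)), "not be monotone")
})

test_that("annual death probability scales qx and caps at one", {
  lt <- data.frame(age = 0:100, qx = c(rep(0.01, 100), 1))
  m <- mortality_model(validate_life_table(lt))
  expect_equal(annual_death_probability(40, "G3", m), 0.01 * 2.13)
  expect_equal(annual_death_probability(40.9, "G3", m), 0.01 * 2.13)  # floor
  expect_equal(annual_death_probability(150, "G1", m), 1)  # terminal clamp

  m_dial <- mortality_model(validate_life_table(
    data.frame(age = 0:100, qx = c(rep(0.5, 100), 1))),
    esrd_substate_weights = c(no_rrt = 0, dialysis = 1, transplant = 0))
  expect_equal(annual_death_probability(40, "G5", m_dial), 1)  # 0.5*6.86 capped

  m0 <- mortality_model(validate_life_table(
    data.frame(age = 0:100, qx = c(rep(0, 100), 1))))
  expect_equal(annual_death_probability(40, "G4", m0), 0)

  # with the default ratio ordering, severity never lowers the probability
  m_def <- mortality_model(fixture_life_table())
  p <- annual_death_probability(60, c("G1", "G2", "G3", "G4", "G5"), m_def)
  expect_true(all(diff(p) >= 0))
})

test_that("malformed life tables are rejected", {
  expect_error(validate_life_table(data.frame(age = 0:99, qx = rep(0.01, 100))),
               "ages 18 to 100")
  expect_error(validate_life_table(
    data.frame(age = c(0:50, 52:101), qx = c(rep(0.01, 101), 1)[1:101])),
    "contiguous")
  expect_error(validate_life_table(
    data.frame(age = 0:100, qx = rep(0.01, 101))), "terminal")
  expect_error(validate_life_table(
    data.frame(age = 0:100, qx = c(rep(1.2, 100), 1))), "\\[0, 1\\]")
})

test_that("life tables round-trip through CSV, with optional sex column", {
  path <- withr::local_tempfile(fileext = ".csv")
  lt <- fixture_life_table()
  write_life_table(lt, path)
  expect_equal(as.data.frame(read_life_table(path)), as.data.frame(lt))

  lt2 <- rbind(cbind(sex = "male", as.data.frame(lt)),
               cbind(sex = "female", as.data.frame(lt)))
  lt2$qx[lt2$sex == "female"] <- pmin(1, lt2$qx[lt2$sex == "female"] * 0.8)
  lt2$qx[lt2$sex == "female" & lt2$age == 100] <- 1
  write_life_table(validate_life_table(lt2), path)
  back <- read_life_table(path)
  expect_equal(lookup_qx_for_test(back, 50, "female"),
               lookup_qx_for_test(back, 50, "male") * 0.8)
})

test_that("engine reproduces life-table life expectancy when ratios are one", {
  # a cohort that never progresses, followed under general-population mortality
  lt <- fixture_life_table()
  m1 <- unit_mortality(lt)
  coh <- patient_stratum("male", "1C", age = 40, egfr = 80)
  arm <- run_arm(coh, coeffs = flat_coeffs(0), mortality = m1, horizon = 75)
  expect_equal(arm$life_years[["total"]],
               life_table_life_expectancy(lt, 40), tolerance = 1e-6)

  # survival fraction (alive occupancy) is non-increasing over cycles
  alive <- rowSums(arm$occupancy[, ckd_stages()])
  expect_true(all(diff(alive) <= 1e-12))
})
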