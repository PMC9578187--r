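test_that("PSA is bitwise reproducible for a fixed seed", {
  coh <- build_base_cohort()
  cfg <- psa_config(n_iterations = 50, seed = 123, sd_annual_effect = 0.15)
  a <- run_psa(cfg, coh, treatment = synthetic_treatment(), horizon = 75)
  b <- run_psa(cfg, coh, treatment = synthetic_treatment(), horizon = 75)
  expect_identical(a$interval, b$interval)
  expect_identical(a$draws, b$draws)

  c2 <- run_psa(psa_config(n_iterations = 50, seed = 124,
                           sd_annual_effect = 0.15),
                coh, treatment = synthetic_treatment(), horizon = 75)
  expect_false(identical(a$interval, c2$interval))
})

test_that("a degenerate distribution collapses to the deterministic delay", {
  coh <- build_base_cohort()
  trt <- synthetic_treatment()
  res <- run_psa(psa_config(n_iterations = 10, seed = 7, sd_annual_effect = 0),
                 coh, treatment = trt, horizon = 75)
  unt <- run_arm(coh, horizon = 75)
  det <- compare_arms(unt, run_arm(coh, treatment = trt, horizon = 75))
  expect_equal(unname(res$interval[1]), det$delay_of_esrd$overall,
               tolerance = 1e-12)
  expect_equal(unname(res$interval[2]), det$delay_of_esrd$overall,
               tolerance = 1e-12)
})

test_that("interval width is self-consistent across PSA sample sizes", {
  coh <- build_base_cohort()
  trt <- synthetic_treatment()
  small <- run_psa(psa_config(n_iterations = 200, seed = 1,
                              sd_annual_effect = 0.15),
                   coh, treatment = trt, horizon = 75)
  large <- run_psa(psa_config(n_iterations = 10000, seed = 1,
                              sd_annual_effect = 0.15),
                   coh, treatment = trt, horizon = 75)
  width <- function(x) unname(diff(x$interval))
  # the small run must agree with the large one within its own Monte-Carlo
  # error, estimated by bootstrapping the 200-draw interval width
  set.seed(99)
  boot_widths <- replicate(500, {
    d <- sample(small$draws$delay_of_esrd, replace = TRUE)
    diff(stats::quantile(d, c(0.025, 0.975)))
  })
  expect_lt(abs(width(small) - width(large)), 3 * stats::sd(boot_widths))
})

test_that("PSA configuration is validated", {
  expect_error(psa_config(n_iterations = 100, sd_annual_effect = 0.1),
               "seed")
  expect_error(psa_config(n_iterations = 1, seed = 1, sd_annual_effect = 0.1),
               "n_iterations")
  expect_error(psa_config(n_iterations = 10, seed = 1), "parameters")
  expect_error(psa_parameter("annual_effect", "normal", mean = 1.2),
               "sd")
  expect_error(psa_parameter("annual_effect", "beta", shape1 = -1, shape2 = 2),
               "shape")
})

test_that("PSA can sample equation coefficients and risk ratios", {
  coh <- patient_stratum("male", "1C", age = 40, egfr = 75, count = 10)
  pars <- list(
    psa_parameter("annual_effect", "normal", mean = 1.2, sd = 0.1, lower = 0),
    psa_parameter("sigma_1C", "normal", mean = -2.63, sd = 0.2, upper = -0.5)
  )
  res <- run_psa(psa_config(n_iterations = 30, seed = 9, parameters = pars),
                 coh, treatment = treatment_spec(1.2, c(0, 0, 0)),
                 horizon = 75)
  expect_equal(nrow(res$draws), 30)
  expect_true(all(c("annual_effect", "sigma_1C", "delay_of_esrd") %in%
                    names(res$draws)))
  expect_true(all(res$draws$delay_of_esrd > 0))
})
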