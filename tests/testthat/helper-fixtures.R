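# Shared fixtures, built in code so every test runs offline.

# Coefficients giving every stratum the same constant annual slope `s`
# (no sex, age or subclass structure) -- handy for closed-form oracles.
flat_coeffs <- function(s) {
  suppressWarnings(irazabal_coefficients(
    epsilon = s, lambda_sex_slope = 0, mu_age_slope = 0,
    sigma = c("1C" = 0, "1D" = 0, "1E" = 0)
  ))
}

fixture_life_table <- function() generate_life_table_fixture()

# All-ratios-one mortality: deaths follow the general-population table alone.
unit_mortality <- function(lt = fixture_life_table()) {
  mortality_model(lt, rr_g1_g2 = 1, rr_g3 = 1, rr_g4_g5_no_rrt = 1,
                  rr_dialysis = 1, rr_transplant = 1)
}

# Synthetic discontinuation schedule used throughout the packaged tests; the
# trial's own rates are not published in the model description.
synthetic_treatment <- function(effect = 1.20) {
  treatment_spec(effect, c(0.15, 0.05, 0.03))
}

lookup_qx_for_test <- function(lt, age, sex = NULL) {
  adpkdprog:::lookup_qx(age, lt, sex)
}

toy_stratum <- function(egfr = 55, age = 40) {
  patient_stratum("male", "1C", age = age, egfr = egfr)
}

# Fine-grid scan oracle for the ESRD crossing time: first time on a 1e-4-year
# grid at which the closed-form trajectory falls below 15.
grid_scan_crossing <- function(stratum, coeffs, modes, modifier = 0,
                               t_max = 60, step = 1e-4) {
  tt <- seq(0, t_max, by = step)
  s <- annual_slope(stratum$sex, stratum$mean_age_years,
                    stratum$mayo_subclass, coeffs, modes)
  q <- if (modes$age_interaction == "current_age") coeffs$mu_age_slope else 0
  anchor <- if (modes$anchoring == "equation_intercept") {
    i <- if (modes$sex_indicator == "male_indicator") {
      as.numeric(stratum$sex == "male")
    } else {
      as.numeric(stratum$sex == "female")
    }
    coeffs$alpha + coeffs$beta_sex * i + coeffs$gamma_age * stratum$mean_age_years +
      coeffs$delta_egfr * stratum$mean_egfr + coeffs$theta[[stratum$mayo_subclass]]
  } else {
    stratum$mean_egfr
  }
  egfr <- anchor + min(0, s + modifier) * tt + q * tt^2
  idx <- which(egfr < 15)
  if (!length(idx)) Inf else tt[idx[1L]]
}
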