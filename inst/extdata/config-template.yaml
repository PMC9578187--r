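# Run-configuration template for the adpkdprog disease-progression model.
# All sections are optional except where noted; omitted keys take the
# packaged defaults.

seed: 1

# "builtin" = packaged 18-stratum base-case cohort; or a path to a cohort CSV
# with columns sex,mayo_subclass,ckd_stage,count,mean_age_years,mean_egfr.
cohort: builtin

equation_modes:
  sex_indicator: female_indicator    # or male_indicator
  age_interaction: baseline_age      # or current_age (adds a quadratic term)
  anchoring: observed_baseline       # or equation_intercept

treatment:
  enabled: true
  annual_effect: 1.20                # mL/min/1.73 m^2 per year
  # PLACEHOLDER values. The TEMPO 3:4 annual discontinuation rates for
  # treatment years 1-3 are not packaged; replace these synthetic values with
  # the trial-derived rates before interpreting treated-arm output. Year 4 is
  # copied from year 3; after year 4 discontinuation occurs only at ESRD.
  discontinuation_probs: [0.15, 0.05, 0.03]

mortality:
  life_table: fixture                # or a CSV path with columns age,qx
  rr_g1_g2: 1.80
  rr_g3: 2.13
  rr_g4_g5_no_rrt: 3.98
  rr_dialysis: 6.86
  rr_transplant: 2.10
  # Assumed ESRD substate mix (no published split); used only to blend the
  # three ESRD mortality risk ratios.
  esrd_substate_weights:
    no_rrt: 0.05
    dialysis: 0.70
    transplant: 0.25

simulation:
  horizon: 75

# Uncomment to enable the probabilistic sensitivity analysis (requires seed).
# psa:
#   n_iterations: 5000
#   sd_annual_effect: 0.15

output:
  directory: "."
  formats: [csv, json]
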