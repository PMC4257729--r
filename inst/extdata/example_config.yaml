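# Example run configuration: reference-fed non-Hispanic white male on
# synthetic growth-chart curves, birth to age 20, all parameters at their
# documented defaults. Units: years at the interface, MJ/day for energy,
# kcal offsets converted with 1 kcal = 0.004184 MJ.
curves:
  source: synthetic          # or "lms" with lms_files: {height: path, bmi: path}
  sex: male
  race: nh_white
subject:
  height_factor: 1.0         # individual potential-height multiplier
  bmi_factor: 1.0            # predisposition to higher reference BMI
  fmi_offset: 0.0            # kg/m^2 fat beyond BMI/race expectation
  pa_factor: 1.0             # physical-activity multiplier
  bioage_multiplier: 1.0     # <1 slow developer, >1 fast
composition:
  lambda_bmi: 0.5            # weight on current BMI in the indicated blend
  gamma: 2.0                 # FMI-vs-BMI elasticity
  age_slope: 0.01            # kg/m^2 per year FMI drift past age 20
  rho_fm: 39.5               # MJ/kg fat mass
  rho_ffm_adult: 5.0         # MJ/kg fat-free mass at adult saturation
metabolic:
  tef_fraction: 0.10
  at_coefficient: 0.25
  at_includes_growth: true
  dep_eff_fm: 0.98
  dep_eff_ffm: 0.85
  pa_scales_with_weight: true
simulation:
  dt: 1.0                    # days
  tau_height: 180.0          # days, height gap-closing time constant
  catchup_cap: 4.0           # max multiple of reference height velocity
  stunt_threshold: 0.85      # BMI/reference ratio where stunting engages
  stunt_floor: 0.60
  correction_tau: 60.0       # days, composition-correction time constant
scenario:
  t_start_years: 0
  t_end_years: 20
  ei_multiplier: 1.0         # multiplier of reference intake
  # windows:                 # piecewise overrides, e.g.
  #   - {from_years: 12, to_years: 15, multiplier: 1.2}
  #   - {from_years: 30.3, to_years: 30.7, offset_kcal_day: -1500}
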