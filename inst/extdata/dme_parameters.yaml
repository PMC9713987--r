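# Reference parameter set: delayed-release dexamethasone implant vs
# aflibercept in treatment-naive diabetic macular edema.
#
# All costs are 2020 euros. Transition probabilities are per 3-month cycle
# over the five better-seeing-eye visual-acuity states, ordered best to
# worst: >20/40, <=20/40 to >20/80, <=20/80 to >20/200, <=20/200 to >20/400,
# <=20/400. Unit-cost SDs equal 20% of the mean (the published variation
# coefficient); resource-use low/high are the ranges sampled uniformly in
# the probabilistic sensitivity analysis.
#
# The first arm listed is the reference strategy (comparator).
#
# Two inputs were never published and ship as clearly labelled synthetic
# stand-ins: the starting visual-acuity distribution (config below) and the
# national life table (Gompertz-Makeham spec below, calibrated to roughly
# 17 years of remaining life expectancy at age 68).
currency: euros_2020
transition_cycle_length_years: 0.25
arms:
  aflibercept:
    drug:
      name: aflibercept_vial
      unit_cost_euros_2020: 588.8
      unit_cost_sd: 139.0
      injections_per_year: 9.8
    transition_matrix:
    - [0.9199, 0.0542, 0.0259, 0.0, 0.0]
    - [0.0153, 0.9046, 0.0542, 0.0259, 0.0]
    - [0.0, 0.0153, 0.9046, 0.0542, 0.0259]
    - [0.0, 0.0, 0.0153, 0.9046, 0.0801]
    - [0.0, 0.0, 0.0, 0.0153, 0.9847]
    resource_use:
    - name: retina_specialist_consultation
      unit_cost_euros_2020: 112.0
      unit_cost_sd: 24.0
      per_year_mean: 12.0
      per_year_low: 6.0
      per_year_high: 18.0
    - name: fundus_photography
      unit_cost_euros_2020: 20.0
      unit_cost_sd: 4.0
      per_year_mean: 12.0
      per_year_low: 6.0
      per_year_high: 18.0
    - name: optical_coherence_tomography
      unit_cost_euros_2020: 149.0
      unit_cost_sd: 30.0
      per_year_mean: 6.0
      per_year_low: 3.0
      per_year_high: 9.0
    - name: fluorescein_angiography
      unit_cost_euros_2020: 42.0
      unit_cost_sd: 8.0
      per_year_mean: 2.0
      per_year_low: 1.0
      per_year_high: 3.0
    adverse_events:
    - name: endophthalmitis
      annual_rate: 0.006
      unit_cost_euros_2020: 3156.0
      unit_cost_sd: 631.0
    - name: lens_damage
      annual_rate: 0.004
      unit_cost_euros_2020: 1600.0
      unit_cost_sd: 320.0
    - name: retinal_detachment
      annual_rate: 0.004
      unit_cost_euros_2020: 3702.0
      unit_cost_sd: 740.0
    rehabilitation_cost_per_year: 69.0
    equipment_cost_per_year: 211.0
    other_annual_cost_euros_2020: 771.0
  dexamethasone:
    drug:
      name: dexamethasone_vial
      unit_cost_euros_2020: 750.92
      unit_cost_sd: 208.0
      injections_per_year: 3.1
    transition_matrix:
    - [0.9863, 0.0107, 0.003, 0.0, 0.0]
    - [0.0979, 0.8884, 0.0107, 0.003, 0.0]
    - [0.0, 0.0979, 0.8884, 0.0107, 0.003]
    - [0.0, 0.0, 0.0979, 0.8884, 0.0137]
    - [0.0, 0.0, 0.0, 0.0979, 0.9021]
    resource_use:
    - name: retina_specialist_consultation
      unit_cost_euros_2020: 112.0
      unit_cost_sd: 24.0
      per_year_mean: 8.0
      per_year_low: 4.0
      per_year_high: 12.0
    - name: fundus_photography
      unit_cost_euros_2020: 20.0
      unit_cost_sd: 4.0
      per_year_mean: 8.0
      per_year_low: 4.0
      per_year_high: 12.0
    - name: optical_coherence_tomography
      unit_cost_euros_2020: 149.0
      unit_cost_sd: 30.0
      per_year_mean: 4.0
      per_year_low: 2.0
      per_year_high: 8.0
    - name: fluorescein_angiography
      unit_cost_euros_2020: 42.0
      unit_cost_sd: 8.0
      per_year_mean: 2.0
      per_year_low: 1.0
      per_year_high: 3.0
    adverse_events:
    - name: endophthalmitis
      annual_rate: 0.0128
      unit_cost_euros_2020: 3156.0
      unit_cost_sd: 631.0
    - name: lens_damage
      annual_rate: 0.006
      unit_cost_euros_2020: 1600.0
      unit_cost_sd: 320.0
    - name: retinal_detachment
      annual_rate: 0.007
      unit_cost_euros_2020: 3702.0
      unit_cost_sd: 740.0
    rehabilitation_cost_per_year: 69.0
    equipment_cost_per_year: 211.0
    other_annual_cost_euros_2020: 1577.0
utilities:
  death_utility: 0.0
  time_trade_off:
  - {state: '>20/40', mean: 0.85, low: 0.75, high: 0.95}
  - {state: '<=20/40 to >20/80', mean: 0.78, low: 0.72, high: 0.84}
  - {state: '<=20/80 to >20/200', mean: 0.78, low: 0.67, high: 0.89}
  - {state: '<=20/200 to >20/400', mean: 0.64, low: 0.53, high: 0.75}
  - {state: '<=20/400', mean: 0.59, low: 0.23, high: 0.95}
  standard_gamble:
  - {state: '>20/40', mean: 0.9, low: 0.83, high: 0.97}
  - {state: '<=20/40 to >20/80', mean: 0.92, low: 0.88, high: 0.96}
  - {state: '<=20/80 to >20/200', mean: 0.84, low: 0.72, high: 0.96}
  - {state: '<=20/200 to >20/400', mean: 0.71, low: 0.58, high: 0.84}
  - {state: '<=20/400', mean: 0.7, low: 0.29, high: 1.11}
shared_costs:
  # Annual DME-comorbidity medical costs and non-medical costs per patient.
  # "category" applies the sum of both figures to both arms (default);
  # "arm" reads the two figures as per-arm totals instead, using each arm's
  # other_annual_cost_euros_2020 above.
  comorbidity_annual_cost_euros_2020: 771.0
  nonmedical_annual_cost_euros_2020: 1577.0
  other_cost_interpretation: category
life_table:
  # SYNTHETIC stand-in for a national (e.g. INE) life table; supply a real
  # two-column CSV (age,qx) via source: csv for substantive analyses.
  source: synthetic_gompertz_makeham
  gompertz_a_per_year: 1.05e-05
  gompertz_b_per_year_age: 0.105
  makeham_c_per_year: 0.0005
  min_age_years: 40
  max_age_years: 100
config:
  cycle_length_years: 0.25
  discount_rate_per_year: 0.035
  starting_age_years: 68.1
  horizon: lifetime
  utility_method: tto
  extrapolation: continuous
  half_cycle_correction: false
  include_indirect_costs: false
  indirect_annual_cost_euros_2020: 2000.0
  rebound_decline_multiplier: 2.0
  rebound_tv_tolerance: 0.01
  starting_distribution:
    # SYNTHETIC placeholder: the originating registry distribution over the
    # five states at treatment initiation is not published.
    source: synthetic_placeholder
    values: [0.25, 0.35, 0.25, 0.1, 0.05]
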