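path,value
arms.dexamethasone.transition_matrix.1.1,0.9863
arms.aflibercept.transition_matrix.1.1,0.9199
arms.dexamethasone.transition_matrix.1.2,0.0107
arms.aflibercept.transition_matrix.1.2,0.0542
arms.dexamethasone.transition_matrix.1.3,0.003
arms.aflibercept.transition_matrix.1.3,0.0259
arms.dexamethasone.transition_matrix.1.4,0
arms.aflibercept.transition_matrix.1.4,0
arms.dexamethasone.transition_matrix.1.5,0
arms.aflibercept.transition_matrix.1.5,0
arms.dexamethasone.transition_matrix.2.1,0.0979
arms.aflibercept.transition_matrix.2.1,0.0153
arms.dexamethasone.transition_matrix.2.2,0.8884
arms.aflibercept.transition_matrix.2.2,0.9046
arms.dexamethasone.transition_matrix.2.3,0.0107
arms.aflibercept.transition_matrix.2.3,0.0542
arms.dexamethasone.transition_matrix.2.4,0.003
arms.aflibercept.transition_matrix.2.4,0.0259
arms.dexamethasone.transition_matrix.2.5,0
arms.aflibercept.transition_matrix.2.5,0
arms.dexamethasone.transition_matrix.3.1,0
arms.aflibercept.transition_matrix.3.1,0
arms.dexamethasone.transition_matrix.3.2,0.0979
arms.aflibercept.transition_matrix.3.2,0.0153
arms.dexamethasone.transition_matrix.3.3,0.8884
arms.aflibercept.transition_matrix.3.3,0.9046
arms.dexamethasone.transition_matrix.3.4,0.0107
arms.aflibercept.transition_matrix.3.4,0.0542
arms.dexamethasone.transition_matrix.3.5,0.003
arms.aflibercept.transition_matrix.3.5,0.0259
arms.dexamethasone.transition_matrix.4.1,0
arms.aflibercept.transition_matrix.4.1,0
arms.dexamethasone.transition_matrix.4.2,0
arms.aflibercept.transition_matrix.4.2,0
arms.dexamethasone.transition_matrix.4.3,0.0979
arms.aflibercept.transition_matrix.4.3,0.0153
arms.dexamethasone.transition_matrix.4.4,0.8884
arms.aflibercept.transition_matrix.4.4,0.9046
arms.dexamethasone.transition_matrix.4.5,0.0137
arms.aflibercept.transition_matrix.4.5,0.0801
arms.dexamethasone.transition_matrix.5.1,0
arms.aflibercept.transition_matrix.5.1,0
arms.dexamethasone.transition_matrix.5.2,0
arms.aflibercept.transition_matrix.5.2,0
arms.dexamethasone.transition_matrix.5.3,0
arms.aflibercept.transition_matrix.5.3,0
arms.dexamethasone.transition_matrix.5.4,0.0979
arms.aflibercept.transition_matrix.5.4,0.0153
arms.dexamethasone.transition_matrix.5.5,0.9021
arms.aflibercept.transition_matrix.5.5,0.9847
utilities.time_trade_off.1.mean,0.85
utilities.standard_gamble.1.mean,0.9
utilities.time_trade_off.1.low,0.75
utilities.standard_gamble.1.low,0.83
utilities.time_trade_off.1.high,0.95
utilities.standard_gamble.1.high,0.97
utilities.time_trade_off.2.mean,0.78
utilities.standard_gamble.2.mean,0.92
utilities.time_trade_off.2.low,0.72
utilities.standard_gamble.2.low,0.88
utilities.time_trade_off.2.high,0.84
utilities.standard_gamble.2.high,0.96
utilities.time_trade_off.3.mean,0.78
utilities.standard_gamble.3.mean,0.84
utilities.time_trade_off.3.low,0.67
utilities.standard_gamble.3.low,0.72
utilities.time_trade_off.3.high,0.89
utilities.standard_gamble.3.high,0.96
utilities.time_trade_off.4.mean,0.64
utilities.standard_gamble.4.mean,0.71
utilities.time_trade_off.4.low,0.53
utilities.standard_gamble.4.low,0.58
utilities.time_trade_off.4.high,0.75
utilities.standard_gamble.4.high,0.84
utilities.time_trade_off.5.mean,0.59
utilities.standard_gamble.5.mean,0.7
utilities.time_trade_off.5.low,0.23
utilities.standard_gamble.5.low,0.29
utilities.time_trade_off.5.high,0.95
utilities.standard_gamble.5.high,1.11
arms.aflibercept.resource_use.1.unit_cost_euros_2020,112
arms.aflibercept.resource_use.1.unit_cost_sd,24
arms.aflibercept.resource_use.1.per_year_mean,12
arms.aflibercept.resource_use.1.per_year_low,6
arms.aflibercept.resource_use.1.per_year_high,18
arms.dexamethasone.resource_use.1.unit_cost_euros_2020,112
arms.dexamethasone.resource_use.1.unit_cost_sd,24
arms.dexamethasone.resource_use.1.per_year_mean,8
arms.dexamethasone.resource_use.1.per_year_low,4
arms.dexamethasone.resource_use.1.per_year_high,12
arms.aflibercept.resource_use.2.unit_cost_euros_2020,20
arms.aflibercept.resource_use.2.unit_cost_sd,4
arms.aflibercept.resource_use.2.per_year_mean,12
arms.aflibercept.resource_use.2.per_year_low,6
arms.aflibercept.resource_use.2.per_year_high,18
arms.dexamethasone.resource_use.2.unit_cost_euros_2020,20
arms.dexamethasone.resource_use.2.unit_cost_sd,4
arms.dexamethasone.resource_use.2.per_year_mean,8
arms.dexamethasone.resource_use.2.per_year_low,4
arms.dexamethasone.resource_use.2.per_year_high,12
arms.aflibercept.resource_use.3.unit_cost_euros_2020,149
arms.aflibercept.resource_use.3.unit_cost_sd,30
arms.aflibercept.resource_use.3.per_year_mean,6
arms.aflibercept.resource_use.3.per_year_low,3
arms.aflibercept.resource_use.3.per_year_high,9
arms.dexamethasone.resource_use.3.unit_cost_euros_2020,149
arms.dexamethasone.resource_use.3.unit_cost_sd,30
arms.dexamethasone.resource_use.3.per_year_mean,4
arms.dexamethasone.resource_use.3.per_year_low,2
arms.dexamethasone.resource_use.3.per_year_high,8
arms.aflibercept.resource_use.4.unit_cost_euros_2020,42
arms.aflibercept.resource_use.4.unit_cost_sd,8
arms.aflibercept.resource_use.4.per_year_mean,2
arms.aflibercept.resource_use.4.per_year_low,1
arms.aflibercept.resource_use.4.per_year_high,3
arms.dexamethasone.resource_use.4.unit_cost_euros_2020,42
arms.dexamethasone.resource_use.4.unit_cost_sd,8
arms.dexamethasone.resource_use.4.per_year_mean,2
arms.dexamethasone.resource_use.4.per_year_low,1
arms.dexamethasone.resource_use.4.per_year_high,3
arms.aflibercept.drug.unit_cost_euros_2020,588.8
arms.aflibercept.drug.unit_cost_sd,139
arms.aflibercept.drug.injections_per_year,9.8
arms.dexamethasone.drug.unit_cost_euros_2020,750.92
arms.dexamethasone.drug.unit_cost_sd,208
arms.dexamethasone.drug.injections_per_year,3.1
arms.aflibercept.adverse_events.1.unit_cost_euros_2020,3156
arms.aflibercept.adverse_events.1.unit_cost_sd,631
arms.aflibercept.adverse_events.1.annual_rate,0.006
arms.dexamethasone.adverse_events.1.unit_cost_euros_2020,3156
arms.dexamethasone.adverse_events.1.unit_cost_sd,631
arms.dexamethasone.adverse_events.1.annual_rate,0.0128
arms.aflibercept.adverse_events.2.unit_cost_euros_2020,1600
arms.aflibercept.adverse_events.2.unit_cost_sd,320
arms.aflibercept.adverse_events.2.annual_rate,0.004
arms.dexamethasone.adverse_events.2.unit_cost_euros_2020,1600
arms.dexamethasone.adverse_events.2.unit_cost_sd,320
arms.dexamethasone.adverse_events.2.annual_rate,0.006
arms.aflibercept.adverse_events.3.unit_cost_euros_2020,3702
arms.aflibercept.adverse_events.3.unit_cost_sd,740
arms.aflibercept.adverse_events.3.annual_rate,0.004
arms.dexamethasone.adverse_events.3.unit_cost_euros_2020,3702
arms.dexamethasone.adverse_events.3.unit_cost_sd,740
arms.dexamethasone.adverse_events.3.annual_rate,0.007
arms.aflibercept.rehabilitation_cost_per_year,69
arms.aflibercept.equipment_cost_per_year,211
arms.dexamethasone.rehabilitation_cost_per_year,69
arms.dexamethasone.equipment_cost_per_year,211
arms.aflibercept.other_annual_cost_euros_2020,771
arms.dexamethasone.other_annual_cost_euros_2020,1577
shared_costs.comorbidity_annual_cost_euros_2020,771
shared_costs.nonmedical_annual_cost_euros_2020,1577
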