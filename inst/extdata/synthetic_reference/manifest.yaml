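format: sdmcea-parameter-set
version: 1
files:
  transitions_rrms: transitions_rrms.csv
  transitions_spms: transitions_spms.csv
  relapse_rates: relapse_rates.csv
  mortality_multipliers: mortality_multipliers.csv
  life_table: life_table.csv
  dmd_profiles: dmd_profiles.csv
  utilities: utilities.csv
  state_costs: state_costs.csv
  strategy_cau: strategy_cau.csv
  strategy_sdm: strategy_sdm.csv
  economics: economics.csv
  settings: settings.csv
note: synthetic stand-in parameter set; strategy profiles and behavioural constants
  are the published values, all other tables are synthetic
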