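key,value
start_age,                37
proportion_male,0.28999999999999998
max_age,               100
cycle_length,                 1
perspective,societal_friction
nonadherent_relapse_multiplier,1.4199999999999999
nonadherent_severe_multiplier,             1.075
edss_stop_level,                 6
half_cycle_correction,FALSE
rr_applies_spms,TRUE
entry_edss0,0.29999999999999999
entry_edss1,              0.25
entry_edss2,0.14999999999999999
entry_edss3,0.10000000000000001
entry_edss4,0.10000000000000001
entry_edss5,0.050000000000000003
entry_edss6,0.050000000000000003
entry_edss7,                 0
entry_edss8,                 0
entry_edss9,                 0
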