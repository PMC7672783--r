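key,value
relapse_cost_mild,               600
relapse_cost_severe,              5000
relapse_disutility_mild,0.040000000000000001
relapse_disutility_severe,              0.11
ae_cost_fraction,             0.012
dispensing_fee_first,                14
dispensing_fee_subsequent,                 7
discount_effects,0.014999999999999999
discount_costs,0.040000000000000001
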