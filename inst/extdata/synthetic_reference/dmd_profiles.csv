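name,line,route,rr_progression,rr_relapse,rr_progression_low,rr_progression_high,annual_drug_cost,admin_cost_first_year,admin_cost_subsequent,monitoring_pretreatment,monitoring_annual,monitoring_post_discontinuation,prescriptions_per_year,cau_discontinuation,trial_discontinuation,adherence_applicable,ae_disutility
alemtuzumab,second,infusion,0.57999999999999996,              0.31,0.46399999999999997,0.72499999999999998,             21000,              6500,              3200,               900,               700,               200,                 0,0.10400000000000001,0.062399999999999997,FALSE,             0.012
dimethyl_fumarate,first,self_administered,0.78000000000000003,0.56000000000000005,0.62400000000000011,0.97500000000000009,             13000,                 0,                 0,               350,               250,               120,                12,             0.214,0.12839999999999999,TRUE,0.0060000000000000001
fingolimod,second,self_administered,0.71999999999999997,0.46000000000000002,0.57599999999999996,0.89999999999999991,             19000,                 0,                 0,               800,               400,               120,                12,             0.106,0.063600000000000004,TRUE,0.0080000000000000002
glatiramer_20_generic,first,self_administered,0.84999999999999998,0.71999999999999997,0.68000000000000005,            1.0625,              5200,                 0,                 0,               200,               150,               120,                12,0.26700000000000002,0.16020000000000001,TRUE,0.0040000000000000001
glatiramer_20_brand,first,self_administered,0.84999999999999998,0.71999999999999997,0.68000000000000005,            1.0625,              7800,                 0,                 0,               200,               150,               120,                12,0.26700000000000002,0.16020000000000001,TRUE,0.0040000000000000001
glatiramer_40_brand,first,self_administered,0.84999999999999998,0.69999999999999996,0.68000000000000005,            1.0625,              8200,                 0,                 0,               200,               150,               120,                12,             0.215,             0.129,TRUE,0.0040000000000000001
interferon_b1a,first,self_administered,0.83999999999999997,0.73999999999999999,0.67200000000000004,              1.05,             10800,                 0,                 0,               300,               220,               120,                12,0.26800000000000002,            0.1608,TRUE,0.0080000000000000002
interferon_b1a_22,first,self_administered,0.85999999999999999,0.72999999999999998,0.68800000000000006,             1.075,             10200,                 0,                 0,               300,               220,               120,                12,0.27100000000000002,0.16259999999999999,TRUE,0.0080000000000000002
interferon_b1a_44,first,self_administered,0.82999999999999996,0.69999999999999996,0.66400000000000003,1.0374999999999999,             11500,                 0,                 0,               300,               220,               120,                12,0.30099999999999999,0.18060000000000001,TRUE,0.0080000000000000002
interferon_b1b,first,self_administered,0.83999999999999997,0.71999999999999997,0.67200000000000004,              1.05,              9800,                 0,                 0,               300,               220,               120,                12,0.25900000000000001,0.15540000000000001,TRUE,0.0080000000000000002
natalizumab,second,infusion,              0.62,0.33000000000000002,             0.496,0.77500000000000002,             17500,              2600,              2600,               600,               450,               200,                 0,              0.13,             0.078,FALSE,              0.01
ocrelizumab,second,infusion,0.59999999999999998,0.34999999999999998,0.47999999999999998,              0.75,             23000,              2200,              2200,               500,               400,               200,                 0,0.13100000000000001,0.078600000000000003,FALSE,0.0080000000000000002
peginterferon_b1a,first,self_administered,0.83999999999999997,0.70999999999999996,0.67200000000000004,              1.05,             11000,                 0,                 0,               300,               220,               120,                12,0.26400000000000001,0.15840000000000001,TRUE,0.0080000000000000002
teriflunomide,first,self_administered,0.80000000000000004,0.69999999999999996,0.64000000000000012,                 1,             12000,                 0,                 0,               400,               280,               120,                12,0.20800000000000002,0.12479999999999999,TRUE,0.0050000000000000001
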