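course,edss,healthcare,community_services,equipment_aids,informal_care,productivity_friction,productivity_human_capital
RRMS,                 0,              1800,                 0,                50,               300,              2600,              6000
RRMS,                 1,              2200,               100,               100,               600,              2600,              7500
RRMS,                 2,              2800,               250,               200,              1100,              2400,              9500
RRMS,                 3,              3600,               500,               350,              1900,              2200,             12000
RRMS,                 4,              4800,               900,               600,              3200,              1900,             15000
RRMS,                 5,              6500,              1500,              1000,              5200,              1500,             18000
RRMS,                 6,              9000,              2600,              1700,              8200,              1000,             21000
RRMS,                 7,             13000,              4200,              2600,             12500,               500,             23000
RRMS,                 8,             19000,              6500,              3800,             18000,               150,             24000
RRMS,                 9,             27000,              9000,              5200,             24000,                 0,             24500
SPMS,                 1,              2420,               100,               100,               600,              2600,              7500
SPMS,                 2,3080.0000000000005,               250,               200,              1100,              2400,              9500
SPMS,                 3,3960.0000000000005,               500,               350,              1900,              2200,             12000
SPMS,                 4,              5280,               900,               600,              3200,              1900,             15000
SPMS,                 5,7150.0000000000009,              1500,              1000,              5200,              1500,             18000
SPMS,                 6,              9900,              2600,              1700,              8200,              1000,             21000
SPMS,                 7,14300.000000000002,              4200,              2600,             12500,               500,             23000
SPMS,                 8,             20900,              6500,              3800,             18000,               150,             24000
SPMS,                 9,29700.000000000004,              9000,              5200,             24000,                 0,             24500
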