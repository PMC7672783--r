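course,edss,relapse_rate,severe_fraction
RRMS,                 0,0.41999999999999998,0.20000000000000001
RRMS,                 1,0.39000000000000001,0.20000000000000001
RRMS,                 2,0.35999999999999999,0.20000000000000001
RRMS,                 3,0.32999999999999996,0.20000000000000001
RRMS,                 4,0.29999999999999999,0.20000000000000001
RRMS,                 5,0.27000000000000002,0.20000000000000001
RRMS,                 6,0.23999999999999999,0.20000000000000001
RRMS,                 7,0.20999999999999999,0.20000000000000001
RRMS,                 8,0.17999999999999999,0.20000000000000001
RRMS,                 9,0.14999999999999997,0.20000000000000001
SPMS,                 1,0.10000000000000001,0.14999999999999999
SPMS,                 2,0.10000000000000001,0.14999999999999999
SPMS,                 3,0.10000000000000001,0.14999999999999999
SPMS,                 4,0.10000000000000001,0.14999999999999999
SPMS,                 5,0.10000000000000001,0.14999999999999999
SPMS,                 6,0.10000000000000001,0.14999999999999999
SPMS,                 7,0.10000000000000001,0.14999999999999999
SPMS,                 8,0.10000000000000001,0.14999999999999999
SPMS,                 9,0.10000000000000001,0.14999999999999999
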