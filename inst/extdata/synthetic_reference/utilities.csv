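course,edss,utility
RRMS,                 0,              0.87
RRMS,                 1,0.81999999999999995
RRMS,                 2,0.76000000000000001
RRMS,                 3,0.68999999999999995
RRMS,                 4,0.60999999999999999
RRMS,                 5,0.52000000000000002
RRMS,                 6,0.41999999999999998
RRMS,                 7,0.29999999999999999
RRMS,                 8,0.17000000000000001
RRMS,                 9,0.029999999999999999
SPMS,                 1,0.77499999999999991
SPMS,                 2,0.71499999999999997
SPMS,                 3,0.64499999999999991
SPMS,                 4,0.56499999999999995
SPMS,                 5,0.47500000000000003
SPMS,                 6,             0.375
SPMS,                 7,             0.255
SPMS,                 8,             0.125
SPMS,                 9,-0.014999999999999999
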