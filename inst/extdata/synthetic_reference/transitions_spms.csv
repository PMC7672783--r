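from_edss,to_spms_edss1,to_spms_edss2,to_spms_edss3,to_spms_edss4,to_spms_edss5,to_spms_edss6,to_spms_edss7,to_spms_edss8,to_spms_edss9
                 1,0.83199999999999996,0.16800000000000001,                 0,                 0,                 0,                 0,                 0,                 0,                 0
                 2,                 0,0.82400000000000007,0.17599999999999999,                 0,                 0,                 0,                 0,                 0,                 0
                 3,                 0,                 0,0.81600000000000006,             0.184,                 0,                 0,                 0,                 0,                 0
                 4,                 0,                 0,                 0,0.80800000000000005,             0.192,                 0,                 0,                 0,                 0
                 5,                 0,                 0,                 0,                 0,0.80000000000000004,0.20000000000000001,                 0,                 0,                 0
                 6,                 0,                 0,                 0,                 0,                 0,0.79200000000000004,0.20800000000000002,                 0,                 0
                 7,                 0,                 0,                 0,                 0,                 0,                 0,0.78400000000000003,             0.216,                 0
                 8,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.77600000000000002,             0.224
                 9,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 1
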