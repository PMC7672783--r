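from_edss,to_rrms_edss0,to_rrms_edss1,to_rrms_edss2,to_rrms_edss3,to_rrms_edss4,to_rrms_edss5,to_rrms_edss6,to_rrms_edss7,to_rrms_edss8,to_rrms_edss9,spms_convert
                 0,             0.875,              0.11,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.014999999999999999
                 1,0.059999999999999998,0.79799999999999993,0.11799999999999999,                 0,                 0,                 0,                 0,                 0,                 0,                 0,             0.024
                 2,                 0,0.059999999999999998,0.78099999999999992,             0.126,                 0,                 0,                 0,                 0,                 0,                 0,0.033000000000000002
                 3,                 0,                 0,0.059999999999999998,0.7639999999999999,0.13400000000000001,                 0,                 0,                 0,                 0,                 0,0.041999999999999996
                 4,                 0,                 0,                 0,0.059999999999999998,0.74699999999999989,0.14200000000000002,                 0,                 0,                 0,                 0,0.050999999999999997
                 5,                 0,                 0,                 0,                 0,0.059999999999999998,0.72999999999999998,0.14999999999999999,                 0,                 0,                 0,0.059999999999999998
                 6,                 0,                 0,                 0,                 0,                 0,0.059999999999999998,0.71299999999999997,             0.158,                 0,                 0,0.068999999999999992
                 7,                 0,                 0,                 0,                 0,                 0,                 0,0.059999999999999998,0.69599999999999995,0.16600000000000001,                 0,             0.078
                 8,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.059999999999999998,0.67900000000000005,0.17399999999999999,0.086999999999999994
                 9,                 0,                 0,                 0,                 0,                 0,                 0,                 0,                 0,0.059999999999999998,0.84399999999999997,0.095999999999999988
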