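edss,multiplier
                 0,                 1
                 1,               1.2
                 2,               1.3
                 3,               1.5
                 4,               1.7
                 5,                 2
                 6,2.3999999999999999
                 7,                 3
                 8,3.8999999999999999
                 9,                 5
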