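parameter,item,value
label,,CAU
initiation,best_supportive_care,              0.25
initiation,alemtuzumab,             0.002
initiation,dimethyl_fumarate,0.33600000000000002
initiation,fingolimod,                 0
initiation,glatiramer_20_generic,             0.002
initiation,glatiramer_20_brand,             0.106
initiation,glatiramer_40_brand,             0.002
initiation,interferon_b1a,              0.01
initiation,interferon_b1a_22,0.0050000000000000001
initiation,interferon_b1a_44,0.0050000000000000001
initiation,interferon_b1b,              0.01
initiation,natalizumab,0.040000000000000001
initiation,ocrelizumab,0.0080000000000000002
initiation,peginterferon_b1a,              0.01
initiation,teriflunomide,             0.214
adherent_proportion,alemtuzumab,                 1
adherent_proportion,dimethyl_fumarate,0.58899999999999997
adherent_proportion,fingolimod,0.58899999999999997
adherent_proportion,glatiramer_20_generic,0.58899999999999997
adherent_proportion,glatiramer_20_brand,0.58899999999999997
adherent_proportion,glatiramer_40_brand,0.58899999999999997
adherent_proportion,interferon_b1a,0.58899999999999997
adherent_proportion,interferon_b1a_22,0.58899999999999997
adherent_proportion,interferon_b1a_44,0.58899999999999997
adherent_proportion,interferon_b1b,0.58899999999999997
adherent_proportion,natalizumab,                 1
adherent_proportion,ocrelizumab,                 1
adherent_proportion,peginterferon_b1a,0.58899999999999997
adherent_proportion,teriflunomide,0.58899999999999997
discontinuation_multiplier,,                 1
sdm_cost_per_decision,,                 0
switch_to_dmd_share,,0.94999999999999996
side_effect_share,,0.79000000000000004
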