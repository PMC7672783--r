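parameter,item,value
label,,SDM
initiation,best_supportive_care,0.19980019980019981
initiation,alemtuzumab,0.002997002997002997
initiation,dimethyl_fumarate,0.41258741258741261
initiation,fingolimod,                 0
initiation,glatiramer_20_generic,0.00099900099900099922
initiation,glatiramer_20_brand,0.034965034965034968
initiation,glatiramer_40_brand,0.00099900099900099922
initiation,interferon_b1a,0.002997002997002997
initiation,interferon_b1a_22,0.0019980019980019984
initiation,interferon_b1a_44,0.0019980019980019984
initiation,interferon_b1b,0.002997002997002997
initiation,natalizumab,0.059940059940059943
initiation,ocrelizumab,0.011988011988011988
initiation,peginterferon_b1a,0.002997002997002997
initiation,teriflunomide,0.26273726273726278
adherent_proportion,alemtuzumab,                 1
adherent_proportion,dimethyl_fumarate,0.63900000000000001
adherent_proportion,fingolimod,0.63900000000000001
adherent_proportion,glatiramer_20_generic,0.63900000000000001
adherent_proportion,glatiramer_20_brand,0.63900000000000001
adherent_proportion,glatiramer_40_brand,0.63900000000000001
adherent_proportion,interferon_b1a,0.63900000000000001
adherent_proportion,interferon_b1a_22,0.63900000000000001
adherent_proportion,interferon_b1a_44,0.63900000000000001
adherent_proportion,interferon_b1b,0.63900000000000001
adherent_proportion,natalizumab,                 1
adherent_proportion,ocrelizumab,                 1
adherent_proportion,peginterferon_b1a,0.63900000000000001
adherent_proportion,teriflunomide,0.63900000000000001
discontinuation_multiplier,,               0.5
sdm_cost_per_decision,,               100
switch_to_dmd_share,,0.94999999999999996
side_effect_share,,0.79000000000000004
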