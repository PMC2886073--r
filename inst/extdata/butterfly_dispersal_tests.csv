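metric,trait_class,n_species,c_mean,p_c_mean,s3,p_s3,sc,p_sc
dispersal_fraction,dispersal propensity,25,0.233,0.208,0.417,0.076,0.307,0.092
alpha1,dispersal ability,16,0.258,0.208,0.578,0.583,0.570,0.628
alpha2,dispersal ability,18,0.542,0.008,0.319,0.014,0.127,0.092
p5km,dispersal ability,27,0.263,0.132,0.307,0.008,0.188,0.102
daily_moves,dispersal ability,25,0.374,0.070,0.381,0.036,0.119,0.015
fst_landscape,dispersal efficiency,13,0.144,0.514,0.450,0.055,0.277,0.008
fst_regional,dispersal efficiency,15,0.063,0.640,0.435,0.583,0.233,0.384
fst_continental,dispersal efficiency,10,0.125,0.514,0.549,0.583,0.104,0.054
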