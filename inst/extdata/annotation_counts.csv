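cohort,label_type,app,site,fp,tp,precision_pct,ci_low_pct,ci_high_pct,rate_per_mm2,ci_fp,ci_tp
primary,tumor,THR_brown,primary,146,1298,89.9,88.2,91.3,962,146,1298
primary,tumor,THR_red,primary,15,2843,99.5,99.1,99.7,1739,15,2843
primary,tumor,CNN_Ann-IHC,primary,92,3597,97.5,97.0,98.0,2245,92,3597
primary,tumor,CNN_Ann-HE_IHC,primary,7,2468,99.7,99.4,99.9,1506,7,2468
primary,normal,THR_red,primary,12,626,98.1,96.7,98.9,388,12,626
primary,normal,CNN_Ann-IHC,primary,25,199,88.8,84.0,92.3,136,25,199
primary,normal,CNN_Ann-HE_IHC,primary,3,373,99.2,97.7,99.7,229,3,373
metastasis,tumor,CNN_Ann-HE_IHC,all,7,2177,99.7,99.3,99.8,614,7,2177
metastasis,tumor,CNN_Ann-HE_IHC,regional_lymph_node,1,405,99.8,98.6,100,312,1,405
metastasis,tumor,CNN_Ann-HE_IHC,distant_lymph_node,2,219,99.1,96.8,99.8,340,2,219
metastasis,tumor,CNN_Ann-HE_IHC,subcutis,4,1127,99.6,99.1,99.9,1392,4,1127
metastasis,tumor,CNN_Ann-HE_IHC,lung,0,421,100,99.1,100,666,0,421
metastasis,tumor,CNN_Ann-HE_IHC,brain,0,5,100,56.6,100,31,0,5
metastasis,normal,CNN_Ann-HE_IHC,all,109,1113,91.1,89.6,92.8,343,109,1148
metastasis,normal,CNN_Ann-HE_IHC,regional_lymph_node,17,393,95.9,93.5,97.4,315,17,393
metastasis,normal,CNN_Ann-HE_IHC,distant_lymph_node,43,499,92.1,89.5,94.1,833,43,499
metastasis,normal,CNN_Ann-HE_IHC,subcutis,0,178,100,97.9,100,219,0,178
metastasis,normal,CNN_Ann-HE_IHC,lung,3,5,62.5,30.6,86.3,13,3,5
metastasis,normal,CNN_Ann-HE_IHC,brain,46,73,61.3,52.4,69.6,733,46,73
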