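# knowledge_version: IWPC-2009 (N Engl J Med 360:753-764, appendix algorithms)
# linear predictors on sqrt(weekly warfarin dose in mg); prediction = predictor^2
model,term,coefficient
pharmacogenetic,intercept,5.6044
pharmacogenetic,age_decades,-0.2614
pharmacogenetic,height_cm,0.0087
pharmacogenetic,weight_kg,0.0128
pharmacogenetic,vkorc1_GA,-0.8677
pharmacogenetic,vkorc1_AA,-1.6974
pharmacogenetic,vkorc1_unknown,-0.4854
pharmacogenetic,cyp2c9_12,-0.5211
pharmacogenetic,cyp2c9_13,-0.9357
pharmacogenetic,cyp2c9_22,-1.0616
pharmacogenetic,cyp2c9_23,-1.9206
pharmacogenetic,cyp2c9_33,-2.3312
pharmacogenetic,cyp2c9_unknown,-0.2188
pharmacogenetic,race_asian,-0.1092
pharmacogenetic,race_black,-0.2760
pharmacogenetic,race_mixed_or_missing,-0.1032
pharmacogenetic,enzyme_inducer,1.1816
pharmacogenetic,amiodarone,-0.5503
clinical,intercept,4.0376
clinical,age_decades,-0.2546
clinical,height_cm,0.0118
clinical,weight_kg,0.0134
clinical,race_asian,-0.6752
clinical,race_black,0.4060
clinical,race_mixed_or_missing,0.0443
clinical,enzyme_inducer,1.2799
clinical,amiodarone,-0.5695
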