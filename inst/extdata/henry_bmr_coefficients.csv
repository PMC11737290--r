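sex,age_min,age_max,weight_coef,height_coef,intercept
male,60,Inf,0.0478,2.26,-1.070
female,60,Inf,0.0356,1.76,0.0448
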