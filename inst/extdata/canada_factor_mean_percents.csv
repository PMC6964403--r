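factor,mean_percent
age_lt10,11.0
age_ge75,7.2
chronic_disease,14.7
pregnancy,0.7
outdoor_work,15.1
less_than_hs,5.3
low_vitc,6.0
remainder_10_19_65_74,12.1
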