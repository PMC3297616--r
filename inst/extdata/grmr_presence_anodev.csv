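term,df,deviance,resid_df,resid_dev,p_value
NULL,NA,NA,591,700.62,NA
days,1,18.06,590,682.55,0.00
ldist,1,158.43,589,524.13,0.00
shark_type,3,6.13,586,517.99,0.11
habitat,2,7.05,584,510.94,0.03
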