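term,df,deviance,resid_df,resid_dev,p_value
NULL,NA,NA,164,582.06,NA
ldist,1,211.33,163,370.73,0
habitat,2,28.31,161,342.42,0.001
ldist:habitat,2,12.57,159,329.85,0.051
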