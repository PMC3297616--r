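term,df,deviance,resid_df,resid_dev,p_value
NULL,NA,NA,364,345.03,NA
sharkmonth,1,14.008,363,331.02,0.000182
taglife,1,7.226,362,323.79,0.007185
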