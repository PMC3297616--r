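site,reserve,n_deployments,n_present,n_multi
GRMR,true,50,16,6
CCMR,true,50,13,6
TU,false,50,6,0
SWC,false,50,2,0
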