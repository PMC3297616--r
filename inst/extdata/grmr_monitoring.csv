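shark_id,n_days,dur_days,mld_km,ri
18,259,359,17.92,0.71
19,361,356,5.44,0.99
20,111,362,5.44,0.30
21,320,360,17.92,0.88
22,84,229,13.74,0.23
23,270,348,5.44,0.74
223,229,359,17.92,0.63
234,348,355,9.15,0.95
235,204,321,1.25,0.56
236,134,426,17.92,0.37
237,43,468,4.33,0.12
238,198,362,8.44,0.54
239,161,475,1.25,0.44
240,17,147,5.80,0.05
3291,24,87,5.56,0.04
3292,215,220,11.56,0.39
3346,86,274,24.21,0.16
3348,386,484,36.46,0.71
3349,76,327,36.36,0.14
3372,69,358,7.61,0.13
3373,170,424,36.46,0.31
3374,50,175,3.14,0.09
3376,146,303,8.53,0.27
3378,17,65,26.59,0.05
3379,136,466,13.11,0.25
3383,143,510,36.46,0.26
3391,534,585,20.81,0.98
3340,403,534,28.50,0.74
3393,458,506,28.50,0.84
4603,47,134,4.66,0.31
4604,5,44,1.25,0.01
4607,189,184,23.92,0.52
4608,236,359,13.58,0.65
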