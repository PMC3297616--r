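shark_id,transmitter_id,tag_type,battery_days,attachment,tag_date,sex,total_length_cm,maturity,tagging_site_label,tag_lat,tag_lon
18,18,V9,365,internal,2007-05-03,F,110,juvenile,MC,16.742,-87.797
19,19,V9,365,internal,2007-05-09,F,119,juvenile,MC,16.742,-87.797
20,20,V9,365,internal,2007-05-01,M,96,juvenile,EL,16.785,-87.757
21,21,V9,365,internal,2007-05-02,M,119,juvenile,EL,16.785,-87.757
22,22,V9,365,internal,2007-05-03,F,66,juvenile,MC,16.742,-87.797
23,23,V9,365,internal,2007-05-16,F,91,juvenile,EL,16.785,-87.757
223,223,V9,365,internal,2007-05-03,F,90,juvenile,MC,16.742,-87.797
234,234,V9,365,internal,2006-05-09,F,80,juvenile,SE,16.700,-87.840
235,235,V9,365,internal,2006-05-25,F,90,juvenile,EL,16.785,-87.757
236,236,V9,365,internal,2006-05-12,M,135,juvenile,SE,16.700,-87.840
237,237,V9,365,internal,2006-05-25,F,85,juvenile,MC,16.742,-87.797
238,238,V9,365,internal,2006-05-03,M,101,juvenile,SE,16.700,-87.840
239,239,V9,365,internal,2006-05-06,M,86,juvenile,EL,16.785,-87.757
240,240,V9,365,internal,2006-05-01,F,120,juvenile,SE,16.700,-87.840
3291,3291,V16,540,external,2006-05-01,F,214,adult,LAG,16.760,-87.820
3292,3292,V16,540,external,2006-10-10,F,214,adult,EL,16.785,-87.757
3346,3346,V16,540,internal,2006-08-15,F,135,juvenile,SE,16.700,-87.840
3348,3348,V16,540,internal,2004-05-05,M,188,adult,MC,16.742,-87.797
3349,3349,V16,540,internal,2004-05-12,F,134,juvenile,SE,16.700,-87.840
3372,3372,V16,540,internal,2006-05-12,F,136,juvenile,SE,16.700,-87.840
3373,3373,V16,540,internal,2005-07-02,F,110,juvenile,SE,16.700,-87.840
3374,3374,V16,540,internal,2005-05-28,F,142,juvenile,SE,16.700,-87.840
3376,3376,V16,540,internal,2006-10-13,F,176,juvenile,SE,16.700,-87.840
3378,3378,V16,540,internal,2007-05-11,F,156,juvenile,NLAG,16.800,-87.790
3379,3379,V16,540,internal,2006-05-09,M,166,adult,SE,16.700,-87.840
3383,3383,V16,540,internal,2005-05-31,F,124,juvenile,SE,16.700,-87.840
3391,3391,V16,540,internal,2005-05-24,M,167,adult,EL,16.785,-87.757
3340,3340,V16,540,internal,2004-05-06,M,197,adult,SE,16.700,-87.840
3393,3393,V16,540,internal,2004-05-06,M,117,juvenile,SE,16.700,-87.840
4603,4603,V16,540,internal,2007-12-18,M,176,adult,MC,16.742,-87.797
4604,4604,V16,540,internal,2007-05-21,F,122,juvenile,WLAG,16.750,-87.850
4607,4607,V16,540,internal,2007-05-07,M,151,juvenile,MC,16.742,-87.797
4608,4608,V16,540,internal,2007-05-07,M,183,adult,SE,16.700,-87.840
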