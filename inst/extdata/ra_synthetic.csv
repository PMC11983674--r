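"study_id","arm1","arm2","sample_size","study_duration_months","disease_duration_years","mtx_use","ra_duration","anti_tnf","prior_drugs_failed","prior_tnf_failure","biologic_combination","naive_biologic"
"ABA-1","ABA","PBO",40,9,7.6,"no","established","no","biologic","yes","no","no"
"ABA-2","ABA","PBO",302,12,14,"no","late","no","biologic","yes","no","no"
"ABA-3","ABA","PBO",210,14,11.7,"no","late","no","biologic","yes","no","no"
"ABA-4","ABA","PBO",401,10,16,"no","late","no","biologic","yes","no","no"
"ADA-1","ADA","PBO",40,11,6.4,"yes","late","yes","DMARDs","no","no","yes"
"ADA-2","ADA","PBO",418,7,5.3,"yes","early","yes","DMARDs","no","no","yes"
"ADA-3","ADA","PBO",162,6,8.3,"yes","early","yes","DMARDs","no","no","yes"
"ADA-4","ADA","PBO",270,9,7.7,"yes","early","yes","DMARDs","no","yes","yes"
"ADA-5","ADA","PBO",337,6,5.4,"yes","established","yes","DMARDs","no","no","yes"
"ADA-6","ADA","PBO",241,10,7,"yes","early","yes","DMARDs","no","no","yes"
"ANA-1","ANA","PBO",73,4,5.8,"yes","early","no","DMARDs","no","no","yes"
"ANA-2","ANA","PBO",337,13,10.9,"yes","established","no","DMARDs","no","no","yes"
"ANA-3","ANA","PBO",321,10,5.9,"yes","late","no","DMARDs","no","no","yes"
"ETA-1","ETA","PBO",338,5,1.3,"yes","established","yes","DMARDs","no","no","yes"
"ETA-2","ETA","PBO",396,3,8.5,"yes","late","yes","DMARDs","no","no","yes"
"ETA-3","ETA","PBO",312,9,9.8,"yes","early","yes","DMARDs","no","no","yes"
"ETA-4","ETA","PBO",114,9,6.2,"yes","late","yes","DMARDs","no","no","yes"
"ETA-5","ETA","PBO",381,7,8.2,"yes","early","yes","DMARDs","no","no","yes"
"ETA-6","ETA","PBO",322,14,6.1,"yes","late","yes","DMARDs","no","no","yes"
"INF-1","INF","PBO",403,11,6.7,"yes","early","yes","DMARDs","no","no","yes"
"INF-2","INF","PBO",407,5,11.6,"yes","late","yes","DMARDs","no","no","yes"
"INF-3","INF","PBO",377,5,7,"yes","established","yes","DMARDs","no","yes","yes"
"INF-4","INF","PBO",152,7,6.1,"yes","established","yes","DMARDs","no","no","yes"
"INF-5","INF","PBO",174,12,3.9,"yes","established","yes","DMARDs","no","yes","yes"
"RIT-1","RIT","PBO",262,12,11.4,"no","established","no","biologic","yes","no","no"
"RIT-2","RIT","PBO",183,10,9.4,"no","late","no","biologic","yes","no","no"
"RIT-3","RIT","PBO",207,5,12.4,"no","late","no","biologic","yes","no","no"
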