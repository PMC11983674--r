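"study_id","arms","sample_size","study_duration_weeks","fev1_inclusion_pct","fvc_inclusion_pct","smoking_pack_years","quality_score","fev1_min_pct","fev1_max_pct","allocation_concealment","double_blinding","withdrawal_description"
"C01","PBO;BUD;BUD+;FOR",793,52,36,58.7,37.1,5,33,48,"adequate","yes","yes"
"C02","PBO;BUD;BUD+;FOR",776,52,36,60.6,39.5,5,33,48,"adequate","yes","yes"
"C03","PBO;FLU;FLU+;SAL",685,24,46.1,61.2,44,5,37,54.4,"adequate","yes","yes"
"C04","PBO;FLU;FLU+;SAL",382,24,49.8,62.3,33.2,3,38.4,59.4,"adequate","yes","yes"
"C05","PBO;FLU;FLU+;SAL",543,26,42.5,65.6,31.9,5,38.2,64.5,"adequate","yes","yes"
"C06","PBO;FLU;FLU+;SAL",1149,12,37.9,48,48.3,2,41.7,62.2,"adequate","yes","yes"
"C07","PBO;FLU;FLU+",1114,12,45.8,53.9,57.7,2,,,"adequate","yes","yes"
"C08","PBO;FLU;FLU+",417,52,41.3,69.9,54.5,4,44.5,75.2,"adequate","yes","yes"
"C09","PBO;FLU;SAL",524,12,58,59.7,34.3,3,39.5,71.3,"adequate","yes","yes"
"C10","PBO;FLU+;SAL",223,24,48.7,66.2,34.2,2,39.8,54.8,"adequate","yes","yes"
"C11","PBO;TIO",699,12,39,57.2,50.5,5,39.7,50.1,"adequate","yes","no"
"C12","PBO;TIO",1017,24,,68,44.3,2,37.6,55.5,"adequate","yes","yes"
"C13","PBO;TIO",865,24,49.6,,,3,,,"adequate","yes","yes"
"C14","PBO;TIO",561,12,47,,36.5,2,37.5,65.5,"adequate","yes","yes"
"C15","SAL;TIO",879,52,33.2,76.8,49,3,37.5,62.7,"adequate","yes","yes"
"C16","SAL;TIO",872,24,41.7,49.3,47.6,3,41.2,56.2,"adequate","yes","yes"
"C17","FLU+;TIO",1159,24,45.9,,,2,36.4,59.5,"adequate","yes","yes"
"C18","FOR;TIO",1065,26,37.8,65,34.8,4,,,"adequate","yes","yes"
"C19","FLU;PBO",558,24,49.5,56.5,,5,36.3,67.8,"adequate","yes","yes"
"C20","FLU;PBO",1080,24,38.6,62.2,41.7,2,32.4,54.7,"adequate","yes","yes"
"C21","FLU;PBO",649,26,38.5,71.7,43.8,4,41.6,53,"adequate","yes","yes"
"C22","FLU;PBO",679,12,33.7,79.7,48.1,4,30.4,64.9,"adequate","yes","yes"
"C23","FLU;PBO",1064,24,43,48,39.4,4,43.2,59,"adequate","yes","yes"
"C24","FLU;PBO",1081,12,41.8,72.3,43.9,2,35.9,49.4,"adequate","yes","yes"
"C25","PBO;SAL",316,52,45.7,61.9,61.3,3,33.7,59.1,"adequate","yes","yes"
"C26","PBO;SAL",701,24,48.3,77.4,54.9,5,36.1,42,"adequate","yes","yes"
"C27","PBO;SAL",1015,26,44.4,62,,4,33.9,44,"adequate","yes","yes"
"C28","PBO;SAL",926,26,49.2,,51.4,3,40.6,60.3,"adequate","yes","yes"
"C29","PBO;SAL",860,12,,,,4,,,"adequate","yes","yes"
"C30","PBO;SAL",1128,52,44.9,,32.1,4,29.5,66.8,"adequate","yes",
"C31","FLU+;PBO",790,24,45.9,59.9,43.6,3,35.3,69.5,"adequate","yes","yes"
"C32","FLU+;PBO",702,24,53.5,54.1,44.9,2,35.1,51.5,"adequate","yes","yes"
"C33","FLU+;PBO",1390,24,44.9,59.7,35.3,2,39.3,76.3,"adequate","yes","yes"
"C34","FLU+;PBO",614,26,48.5,51.2,47.5,2,37.3,57.8,"adequate","yes","yes"
"C35","FLU+;PBO",786,12,43.3,71.1,44.6,3,39.5,47.7,"adequate","yes","yes"
"C36","FLU+;PBO",312,52,42.4,58.9,50.7,5,44.9,42,"adequate","yes","yes"
"C37","FLU+;PBO",628,52,51.5,,38,5,35.4,48.5,"adequate","yes","yes"
"C38","FOR;PBO",190,52,47.5,56.7,54.1,5,,,"adequate","yes","yes"
"C39","BUD;PBO",950,52,36,62.9,,5,33,48,"adequate","yes","yes"
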