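"patient_id","side","age","weight","sex","ecog","urinalysis_protein","serum_creatinine","creatinine_uln","biopsy_ccrcc","m_stage","mskcc_risk","registered","dosed","central_review_excluded"
"P01","left",69,82,"male",0,0,1,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P02","left",55,74.5,"female",0,0,0.8,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P03","right",72,90,"male",1,1,1.2,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P04","right",61,68,"male",0,0,0.9,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P05","right",49,77,"female",0,0,0.7,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P06","left",66,85,"male",1,0,1.1,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P07","right",58,71,"male",0,1,1,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P08","right",74,94,"male",1,0,1.3,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P09","left",63,66,"female",0,0,0.8,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P10","right",70,88,"male",0,0,1,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P11","right",52,79,"male",1,0,0.9,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P12","left",67,72,"female",0,1,1.1,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P13","right",59,83,"male",0,0,1.2,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P14","left",71,69,"male",1,0,1,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P15","right",64,91,"female",0,0,0.9,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P16","left",56,76,"male",1,0,1.4,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P17","right",68,87,"male",0,1,1,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P18","left",62,70,"female",0,0,0.8,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
"P19","right",75,80,"male",1,0,1.1,1.2,TRUE,"M1","intermediate",TRUE,TRUE,FALSE
"P20","left",78,73,"male",0,0,1.2,1.2,TRUE,"M0",NA,TRUE,TRUE,FALSE
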