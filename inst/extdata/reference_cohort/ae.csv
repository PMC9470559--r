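"patient_id","term","grade","related"
"P01","hypertension",2,TRUE
"P01","hypertension",3,TRUE
"P02","hypertension",1,TRUE
"P03","fatigue",1,TRUE
"P05","diarrhoea",2,TRUE
"P06","hypertension",2,TRUE
"P08","fatigue",2,TRUE
"P08","fatigue",2,TRUE
"P10","diarrhoea",1,TRUE
"P13","dysphonia",1,TRUE
"P15","hypertension",3,TRUE
"P19","fatigue",1,FALSE
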