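"patient_id","phase","approach","incision_rank","level_of_control","venovenous_bypass","hypothermic_cardiac_arrest","pringle"
"P01","planned","open",2,1,FALSE,FALSE,FALSE
"P01","performed","minimally_invasive",1,1,FALSE,FALSE,FALSE
"P02","planned","open",2,2,FALSE,FALSE,FALSE
"P02","performed","open",2,1,FALSE,FALSE,FALSE
"P03","planned","minimally_invasive",1,1,FALSE,FALSE,FALSE
"P03","performed","minimally_invasive",1,1,FALSE,FALSE,FALSE
"P04","planned","minimally_invasive",1,1,FALSE,FALSE,FALSE
"P04","performed","minimally_invasive",1,1,FALSE,FALSE,FALSE
"P05","planned","open",2,2,FALSE,FALSE,FALSE
"P05","performed","open",1,1,FALSE,FALSE,FALSE
"P06","planned","open",2,2,FALSE,FALSE,FALSE
"P06","performed","open",2,2,FALSE,FALSE,FALSE
"P08","planned","open",3,3,FALSE,FALSE,FALSE
"P08","performed","open",2,2,FALSE,FALSE,FALSE
"P09","planned","open",2,2,FALSE,FALSE,FALSE
"P09","performed","open",2,2,FALSE,FALSE,FALSE
"P10","planned","open",2,3,FALSE,FALSE,FALSE
"P10","performed","open",2,3,FALSE,FALSE,FALSE
"P11","planned","open",3,3,FALSE,FALSE,FALSE
"P11","performed","open",3,3,FALSE,FALSE,FALSE
"P12","planned","open",3,3,FALSE,FALSE,FALSE
"P12","performed","open",3,3,FALSE,FALSE,FALSE
"P13","planned","open",2,2,FALSE,FALSE,FALSE
"P13","performed","open",2,2,FALSE,FALSE,FALSE
"P14","planned","open",3,2,FALSE,FALSE,FALSE
"P14","performed","open",2,2,FALSE,FALSE,FALSE
"P15","planned","open",3,3,FALSE,FALSE,FALSE
"P15","performed","open",3,3,FALSE,FALSE,FALSE
"P17","planned","open",4,5,FALSE,FALSE,FALSE
"P17","performed","open",3,3,FALSE,FALSE,FALSE
"P18","planned","open",4,5,FALSE,FALSE,FALSE
"P18","performed","open",4,5,FALSE,FALSE,FALSE
"P19","planned","open",5,6,FALSE,TRUE,FALSE
"P19","performed","open",4,4,FALSE,FALSE,FALSE
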