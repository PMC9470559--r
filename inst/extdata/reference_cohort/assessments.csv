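"patient_id","timepoint","side","tip_landmark","tip_distance_mm","rv_mm","ivc_above_mm","ivc_below_mm","target_sum_mm","new_lesion"
"P01","baseline","left","rv_main",NA,40,0,0,100,FALSE
"P01","week3","left","rv_main",NA,32,0,0,98,FALSE
"P01","week9","left","rv_lateral_to_gonadal",NA,22,0,0,65,FALSE
"P02","baseline","left","rv_lateral_to_gonadal",NA,30,0,0,88,FALSE
"P02","week3","left","rv_lateral_to_gonadal",NA,29,0,0,88,FALSE
"P02","week9","left","rv_lateral_to_gonadal",NA,27,0,0,84,FALSE
"P03","baseline","right","rv_main",NA,50,0,0,120,FALSE
"P03","week3","right","rv_main",NA,49.5,0,0,119,FALSE
"P03","week9","right","rv_main",NA,49,0,0,112,FALSE
"P04","baseline","right","rv_branches",NA,20,0,0,70,FALSE
"P04","week3","right","rv_branches",NA,20,0,0,70,FALSE
"P04","week9","right","rv_branches",NA,20,0,0,69,FALSE
"P05","baseline","right","ivc",15,30,15,5,120,FALSE
"P05","week3","right","ivc",15,26,15,6,115,FALSE
"P05","week9","right","rv_main",NA,24.5,0,0,80,FALSE
"P06","baseline","left","ivc",10,35,10,5,95,FALSE
"P06","week3","left","ivc",10,33,9,5,95,FALSE
"P06","week9","left","ivc",10,31,8,5,92,FALSE
"P07","baseline","right","ivc",19,25,19,6,105,FALSE
"P07","week3","right","ivc",19,25.5,19,6.5,106,FALSE
"P07","week9","right","ivc",19.5,26,19.5,7,107,FALSE
"P08","baseline","right","ivc",40,40,40,10,110,FALSE
"P08","week3","right","ivc",25,40,25,10,104,FALSE
"P08","week9","right","ivc",10.5,38,10.5,10,75,FALSE
"P09","baseline","left","ivc",25,35,25,10,90,FALSE
"P09","week3","left","ivc",20,32,20,8,89,FALSE
"P09","week9","left","ivc",15.4,30,15.4,5,85,FALSE
"P10","baseline","right","ivc",20,30,20,10,100,FALSE
"P10","week3","right","ivc",12,28,12,8,97,FALSE
"P10","week9","right","ivc",5,26,5,5,96,FALSE
"P11","baseline","right","ivc",55,45,55,10,130,FALSE
"P11","week3","right","ivc",50,41.2,50,10,126,FALSE
"P12","baseline","left","ivc",70,40,70,15,140,FALSE
"P12","week3","left","ivc",55,35,55,15,135,FALSE
"P13","baseline","right","ivc",30,30,30,10,96,FALSE
"P13","week3","right","ivc",29,29,29,10,96,FALSE
"P13","week9","right","ivc",28.5,28,28.5,10,94,FALSE
"P14","baseline","left","ivc",45,35,45,20,125,FALSE
"P14","week3","left","ivc",38,30,38,15,121,FALSE
"P14","week9","left","ivc",31,25,31,10,118,FALSE
"P15","baseline","right","ivc",60,40,60,20,90,FALSE
"P15","week3","right","ivc",63,42,63,21,91,FALSE
"P15","week9","right","ivc",66,44,66,22,110,FALSE
"P16","baseline","left","ivc",80,45,80,15,100,FALSE
"P16","week3","left","ivc",88,49.5,88,16.5,100,FALSE
"P16","week9","left","ivc",96,54,96,18,102,TRUE
"P17","baseline","right","ivc_hepatic_below_diaphragm",NA,40,100,20,150,FALSE
"P17","week3","right","ivc_hepatic_below_diaphragm",NA,36,85,15,147,FALSE
"P17","week9","right","ivc",50,47.2,50,10,140,FALSE
"P18","baseline","left","ivc_hepatic_below_diaphragm",NA,35,110,15,135,FALSE
"P18","week3","left","ivc_hepatic_below_diaphragm",NA,33,105,14,134,FALSE
"P18","week9","left","ivc_hepatic_below_diaphragm",NA,32,100,13.6,130,FALSE
"P19","baseline","right","ivc_above_diaphragm",NA,40,180,20,160,FALSE
"P19","week3","right","ivc_above_diaphragm",NA,36,152,16,158,FALSE
"P19","week9","right","ivc_hepatic_below_diaphragm",NA,40.6,110,15,150,FALSE
"P20","baseline","left","ivc_above_diaphragm",NA,45,200,25,170,FALSE
"P20","week3","left","ivc_above_diaphragm",NA,50,232.5,28,172,FALSE
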