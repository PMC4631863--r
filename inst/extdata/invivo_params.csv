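table,group_label,timepoint,mean,sd,n
amylase_activity,control,day15,404.6,5.37,6
amylase_activity,diabetic_control,day15,386.6,31.25,6
amylase_activity,therapeutic,day15,228.3,68.70,6
blood_glucose,control,day0,111,7.9,6
blood_glucose,diabetic_control,day0,332,118.8,6
blood_glucose,therapeutic,day0,399,82.7,6
blood_glucose,control,week2,113,10.5,6
blood_glucose,diabetic_control,week2,314,98.9,6
blood_glucose,therapeutic,week2,114,21.3,6
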