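"subject_id","joint","left_share","right_share"
"S001","elbow",0.475123,0.524877
"S001","neck",0.5,0.5
"S001","shoulder",0.454832,0.545168
"S002","elbow",0.439026,0.560974
"S002","neck",0.5,0.5
"S002","shoulder",0.469562,0.530438
"S003","elbow",0.47019,0.52981
"S003","neck",0.5,0.5
"S003","shoulder",0.482114,0.517886
"S004","elbow",0.453769,0.546231
"S004","neck",0.5,0.5
"S004","shoulder",0.498532,0.501468
"S005","elbow",0.464353,0.535647
"S005","neck",0.5,0.5
"S005","shoulder",0.453285,0.546715
"S006","elbow",0.477476,0.522524
"S006","neck",0.5,0.5
"S006","shoulder",0.466317,0.533683
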