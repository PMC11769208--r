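"id","sex","age","height_cm","weight_kg","readiness_score","readiness_group","no_belt_share","belt_share"
"S001","male",26.841,165.073,59.5189,7,"medium",0.666667,0.333333
"S002","male",31.5859,175.47,70.7704,4,"low",0.666667,0.333333
"S003","male",27.6175,175.875,90.7471,8,"medium",0.666667,0.333333
"S004","female",53.5732,159.306,77.6663,9,"high",0.666667,0.333333
"S005","female",48.5074,174.509,77.7134,8,"medium",0.666667,0.333333
"S006","female",20.516,173.453,96.8916,5,"low",0.666667,0.333333
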