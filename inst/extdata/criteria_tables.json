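{"neck":{"region":"neck","rounding_mode":"exact","notes":"the 'high' physical-readiness likelihood 0.161 is kept as published; it is an outlier versus every other likelihood (~0.9-1.1) and may reflect a transcription error","criteria":[{"name":"physical_readiness","weight_score":1,"kind":"categorical","levels":{"low":1.018,"medium":0.901,"high":0.161}},{"name":"sex","weight_score":1,"kind":"categorical","levels":{"male":1.12,"female":0.93}},{"name":"technique_scenario","weight_score":1,"kind":"proportional","levels":{"no_belt":0.952,"belt":1.024}},{"name":"amplitude","weight_score":1,"kind":"parametric"},{"name":"moment","weight_score":1,"kind":"parametric"},{"name":"cumulative_moment","weight_score":2,"kind":"parametric"}]},"shoulder":{"region":"shoulder","rounding_mode":"exact","notes":null,"criteria":[{"name":"physical_readiness","weight_score":1,"kind":"categorical","levels":{"low":1.009,"medium":0.997,"high":1.03}},{"name":"sex","weight_score":1,"kind":"categorical","levels":{"male":1.016,"female":0.991}},{"name":"technique_scenario","weight_score":1,"kind":"proportional","levels":{"no_belt":0.919,"belt":1.041}},{"name":"symmetry","weight_score":2,"kind":"proportional","levels":{"left":1.009,"right":0.998}},{"name":"amplitude","weight_score":1,"kind":"parametric"},{"name":"moment","weight_score":1,"kind":"parametric"},{"name":"cumulative_moment","weight_score":2,"kind":"parametric"}]},"elbow":{"region":"elbow","rounding_mode":"exact","notes":null,"criteria":[{"name":"physical_readiness","weight_score":1,"kind":"categorical","levels":{"low":1.008,"medium":0.998,"high":1.029}},{"name":"sex","weight_score":1,"kind":"categorical","levels":{"male":1.019,"female":0.989}},{"name":"technique_scenario","weight_score":1,"kind":"proportional","levels":{"no_belt":0.976,"belt":1.017}},{"name":"symmetry","weight_score":2,"kind":"proportional","levels":{"left":1.005,"right":0.999}},{"name":"amplitude","weight_score":1,"kind":"parametric"},{"name":"moment","weight_score":1,"kind":"parametric"},{"name":"cumulative_moment","weight_score":2,"kind":"parametric"}]}}
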