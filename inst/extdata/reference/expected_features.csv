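"subject_id","joint","side","rom_deg","max_moment_Nm","cumulative_moment_Nms"
"S001","elbow","left",94.3342,39.2268,78.4536
"S001","elbow","right",98.9022,43.3346,86.6692
"S001","neck","midline",50.3913,28.9333,57.8666
"S001","shoulder","left",138.94,57.5703,115.141
"S001","shoulder","right",137.691,69.0046,138.009
"S002","elbow","left",97.4033,43.7768,87.5536
"S002","elbow","right",94.6907,55.9366,111.873
"S002","neck","midline",49.7673,36.728,73.456
"S002","shoulder","left",133.137,73.7101,147.42
"S002","shoulder","right",132.761,83.2661,166.532
"S003","elbow","left",102.494,58.8206,117.641
"S003","elbow","right",100.437,66.279,132.558
"S003","neck","midline",48.7272,43.8868,87.7736
"S003","shoulder","left",134.252,94.2514,188.503
"S003","shoulder","right",130.138,101.245,202.489
"S004","elbow","left",88.1201,44.8067,89.6134
"S004","elbow","right",87.6353,53.9366,107.873
"S004","neck","midline",45.8391,37.5502,75.1004
"S004","shoulder","left",114.397,79.359,158.718
"S004","shoulder","right",120.409,79.8264,159.653
"S005","elbow","left",90.7903,51.501,103.002
"S005","elbow","right",91.4975,59.408,118.816
"S005","neck","midline",45.5987,38.4072,76.8143
"S005","shoulder","left",112.577,75.2174,150.435
"S005","shoulder","right",119.237,90.7209,181.442
"S006","elbow","left",90.067,66.3035,132.607
"S006","elbow","right",91.9873,72.5588,145.118
"S006","neck","midline",46.7233,47.2755,94.5511
"S006","shoulder","left",118.239,101.411,202.823
"S006","shoulder","right",115.585,116.062,232.123
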