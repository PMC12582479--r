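"modality","condition","t","value"
"vas","T_26-26",1,27.56
"vas","T_26-26",2,32.23
"vas","T_26-26",3,32.05
"vas","T_26-26",4,31.25
"vas","T_26-26",5,32.24
"vas","T_26-26",6,33.17
"vas","T_26-26",7,34.94
"vas","T_26-26",8,33.57
"vas","T_26-26",9,31.92
"vas","T_26-26",10,32.91
"vas","T_26-26",11,31.01
"vas","T_26-26",12,31.55
"vas","T_26-26",13,26.96
"vas","T_26-26",14,29.15
"vas","T_26-26",15,30.88
"vas","T_26-26",16,31.93
"vas","T_26-26",17,29.74
"vas","T_26-26",18,29.78
"vas","T_26-26",19,29.64
"vas","T_26-26",20,29.91
"vas","T_26-26",21,28.67
"vas","T_26-26",22,28.55
"vas","T_26-26",23,29.61
"vas","T_26-26",24,30.28
"vas","T_26-26",25,33.77
"vas","T_26-26",26,35.54
"vas","T_26-26",27,33.86
"vas","T_26-26",28,35.76
"vas","T_26-26",29,37.72
"vas","T_26-26",30,38.92
"vas","T_26-26",31,42.54
"vas","T_26-31",1,28.67
"vas","T_26-31",2,29.8
"vas","T_26-31",3,36.32
"vas","T_26-31",4,35.49
"vas","T_26-31",5,36.42
"vas","T_26-31",6,34.87
"vas","T_26-31",7,32.65
"vas","T_26-31",8,33.67
"vas","T_26-31",9,28.77
"vas","T_26-31",10,29.68
"vas","T_26-31",11,37.24
"vas","T_26-31",12,33.68
"vas","T_26-31",13,38.78
"vas","T_26-31",14,39.63
"vas","T_26-31",15,34.15
"vas","T_26-31",16,39.16
"vas","T_26-31",17,35.1
"vas","T_26-31",18,34.48
"vas","T_26-31",19,40.12
"vas","T_26-31",20,40.46
"vas","T_26-31",21,46.33
"vas","T_26-31",22,43.44
"vas","T_26-31",23,44.39
"vas","T_26-31",24,42
"vas","T_26-31",25,45.88
"vas","T_26-31",26,45.66
"vas","T_26-31",27,51.13
"vas","T_26-31",28,53.05
"vas","T_26-31",29,56.43
"vas","T_26-31",30,57.76
"vas","T_26-31",31,57.75
"vas","T_26-36",1,28.24
"vas","T_26-36",2,26.83
"vas","T_26-36",3,33.96
"vas","T_26-36",4,37.02
"vas","T_26-36",5,39.9
"vas","T_26-36",6,37.13
"vas","T_26-36",7,37.34
"vas","T_26-36",8,37.81
"vas","T_26-36",9,32.62
"vas","T_26-36",10,34.31
"vas","T_26-36",11,36.92
"vas","T_26-36",12,36.35
"vas","T_26-36",13,39.34
"vas","T_26-36",14,39.52
"vas","T_26-36",15,35.09
"vas","T_26-36",16,40.64
"vas","T_26-36",17,35.87
"vas","T_26-36",18,37.87
"vas","T_26-36",19,39.34
"vas","T_26-36",20,43.21
"vas","T_26-36",21,49.63
"vas","T_26-36",22,43.41
"vas","T_26-36",23,42.4
"vas","T_26-36",24,44.9
"vas","T_26-36",25,48.19
"vas","T_26-36",26,46.78
"vas","T_26-36",27,49.91
"vas","T_26-36",28,55.32
"vas","T_26-36",29,56.71
"vas","T_26-36",30,58.14
"vas","T_26-36",31,57.62
"vas","T_21-36",1,26.49
"vas","T_21-36",2,30.36
"vas","T_21-36",3,35.21
"vas","T_21-36",4,38.05
"vas","T_21-36",5,38.44
"vas","T_21-36",6,36.24
"vas","T_21-36",7,33.89
"vas","T_21-36",8,39.18
"vas","T_21-36",9,34.73
"vas","T_21-36",10,35
"vas","T_21-36",11,39.94
"vas","T_21-36",12,43.64
"vas","T_21-36",13,43.94
"vas","T_21-36",14,43.84
"vas","T_21-36",15,44.79
"vas","T_21-36",16,44.69
"vas","T_21-36",17,45.17
"vas","T_21-36",18,43.51
"vas","T_21-36",19,48.92
"vas","T_21-36",20,52.39
"vas","T_21-36",21,53.31
"vas","T_21-36",22,57.3
"vas","T_21-36",23,55.92
"vas","T_21-36",24,58.24
"vas","T_21-36",25,57
"vas","T_21-36",26,60.26
"vas","T_21-36",27,62.55
"vas","T_21-36",28,71.69
"vas","T_21-36",29,69.4
"vas","T_21-36",30,72.64
"vas","T_21-36",31,75.01
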