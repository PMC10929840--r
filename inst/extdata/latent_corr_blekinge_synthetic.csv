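"","gait","adl","iadl","mmse","comorb","sex","age"
"gait",1,-0.3,-0.35,0.3,-0.2,0,-0.4
"adl",-0.3,1,0.4,-0.25,0.25,0,0.3
"iadl",-0.35,0.4,1,-0.3,0.25,0.05,0.35
"mmse",0.3,-0.25,-0.3,1,-0.15,0,-0.35
"comorb",-0.2,0.25,0.25,-0.15,1,0.05,0.25
"sex",0,0,0.05,0,0.05,1,0.1
"age",-0.4,0.3,0.35,-0.35,0.25,0.1,1
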