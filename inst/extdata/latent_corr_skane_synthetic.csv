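"","gait","adl","iadl","mmse","comorb","sex","age"
"gait",1,-0.27,-0.315,0.27,-0.18,0,-0.36
"adl",-0.27,1,0.36,-0.225,0.225,0,0.27
"iadl",-0.315,0.36,1,-0.27,0.225,0.045,0.315
"mmse",0.27,-0.225,-0.27,1,-0.135,0,-0.315
"comorb",-0.18,0.225,0.225,-0.135,1,0.045,0.225
"sex",0,0,0.045,0,0.045,1,0.09
"age",-0.36,0.27,0.315,-0.315,0.225,0.09,1
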