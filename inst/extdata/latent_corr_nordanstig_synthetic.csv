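"","gait","adl","iadl","mmse","comorb","sex","age"
"gait",1,-0.33,-0.385,0.33,-0.22,0,-0.44
"adl",-0.33,1,0.44,-0.275,0.275,0,0.33
"iadl",-0.385,0.44,1,-0.33,0.275,0.055,0.385
"mmse",0.33,-0.275,-0.33,1,-0.165,0,-0.385
"comorb",-0.22,0.275,0.275,-0.165,1,0.055,0.275
"sex",0,0,0.055,0,0.055,1,0.11
"age",-0.44,0.33,0.385,-0.385,0.275,0.11,1
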