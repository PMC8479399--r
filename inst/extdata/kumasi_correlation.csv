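"","As","Cr","Cu","Fe","Mn","Ni","Zn","Cd"
"As",1,0.398,0.325,0.386,0.17,0.334,0.128,0.942
"Cr",0.398,1,0.372,0.712,0.605,0.641,0.025,0.511
"Cu",0.325,0.372,1,0.533,0.378,0.516,0.455,0.518
"Fe",0.386,0.712,0.533,1,0.763,0.814,0.064,0.532
"Mn",0.17,0.605,0.378,0.763,1,0.84,0.016,0.339
"Ni",0.334,0.641,0.516,0.814,0.84,1,0.012,0.479
"Zn",0.128,0.025,0.455,0.064,0.016,0.012,1,0.387
"Cd",0.942,0.511,0.518,0.532,0.339,0.479,0.387,1
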