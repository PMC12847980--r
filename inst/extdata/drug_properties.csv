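drug,BP,MV,MR,MW,HAC,CO,EV,MP
linolenic acid,496,256.9,89.97,278.44,22,287,93.7,164.33
serine,304.87,91.2,21.88,105.09,10,102,72.5,139.6
methionine,327.23,105.4,37.35,149.21,14,128,78.0,135.72
tyrosine,457.27,164.2,46.62,181.19,16,174,90.2,284.54
cystine,636.49,177.5,53.89,240.29,18,195,84.6,410.25
succinic acid,309.01,106.2,21.93,118.09,10,82,73.9,182.39
N-acetylglucosamine,650.56,227.3,49.13,221.21,21,241,96.4,297.76
glutamic acid,403.96,127.6,30.33,147.13,13,115,76.5,261.92
glycine,190.49,64.1,16.02,75.07,7,55,62.8,82.51
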