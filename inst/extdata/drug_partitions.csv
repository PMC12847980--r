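drug,a,b,count
linolenic acid,1,2,1
linolenic acid,1,3,2
linolenic acid,2,2,15
linolenic acid,2,3,1
serine,1,2,1
serine,1,3,3
serine,2,3,1
serine,3,3,1
methionine,1,2,1
methionine,1,3,3
methionine,2,2,2
methionine,2,3,1
methionine,3,3,1
tyrosine,1,3,3
tyrosine,1,4,2
tyrosine,2,2,2
tyrosine,2,3,5
tyrosine,2,4,1
tyrosine,3,4,1
cystine,1,3,6
cystine,2,2,3
cystine,2,3,2
cystine,3,3,2
succinic acid,1,3,4
succinic acid,2,2,1
succinic acid,2,3,2
N-acetylglucosamine,1,2,1
N-acetylglucosamine,1,3,7
N-acetylglucosamine,2,3,3
N-acetylglucosamine,3,3,4
glutamic acid,1,3,5
glutamic acid,2,2,1
glutamic acid,2,3,2
glutamic acid,3,3,1
glycine,1,2,1
glycine,1,3,2
glycine,2,3,1
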