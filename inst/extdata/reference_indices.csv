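drug,M1,M2,H,F,SS,ABC,RI,SC,GA,HZ
linolenic acid,76.0000,74.0000,9.5667,158.0000,18.6440,13.6538,9.7701,9.5246,18.6547,306.0000
serine,26.0000,26.0000,2.9000,66.0000,5.7348,4.5304,3.1807,2.9328,5.5207,118.0000
methionine,34.0000,34.0000,3.9000,82.0000,7.7348,5.9446,4.1807,3.9328,7.5207,150.0000
tyrosine,68.0000,75.0000,5.9190,190.0000,14.3282,10.4839,6.4155,6.4167,13.0296,340.0000
cystine,58.0000,60.0000,5.9667,146.0000,12.8365,9.7678,6.4473,6.2109,12.1557,266.0000
succinic acid,30.0000,28.0000,3.3000,74.0000,6.6550,5.3873,3.6259,3.3944,6.4237,130.0000
N-acetylglucosamine,70.0000,77.0000,6.7000,186.0000,15.0640,11.2106,7.3066,7.0520,13.9444,340.0000
glutamic acid,40.0000,40.0000,4.1333,102.0000,8.7458,6.8705,4.5366,4.3027,8.2897,182.0000
glycine,16.0000,14.0000,2.0667,38.0000,3.6440,3.0472,2.2701,2.0246,3.6547,66.0000
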