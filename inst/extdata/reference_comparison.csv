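property,form,predictors,R2,winner
BP,linear,HZ,0.760,FALSE
BP,quadratic,H,0.849,TRUE
BP,logarithmic,"F,HZ",0.791,FALSE
MV,linear,RI,0.967,FALSE
MV,quadratic,RI,0.968,TRUE
MV,logarithmic,H,0.933,FALSE
MR,linear,H,0.955,FALSE
MR,quadratic,H,0.965,TRUE
MR,logarithmic,H,0.868,FALSE
MW,linear,NA,NA,FALSE
MW,quadratic,H,0.950,TRUE
MW,logarithmic,H,0.942,FALSE
HAC,linear,ABC,0.927,FALSE
HAC,quadratic,H,0.957,TRUE
HAC,logarithmic,RI,0.949,FALSE
CO,linear,RI,0.962,FALSE
CO,quadratic,RI,0.963,TRUE
CO,logarithmic,H,0.928,FALSE
EV,linear,M2,0.955,FALSE
EV,quadratic,M2,0.958,TRUE
EV,logarithmic,"M1,M2",0.947,FALSE
MP,linear,NA,NA,FALSE
MP,quadratic,H,0.760,TRUE
MP,logarithmic,NA,NA,FALSE
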