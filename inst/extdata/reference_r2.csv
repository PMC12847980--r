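form,property,index,R2,flagged
linear,BP,M2,0.756,FALSE
linear,BP,F,0.756,FALSE
linear,BP,HZ,0.76,FALSE
linear,MV,M1,0.914,FALSE
linear,MV,M2,0.859,FALSE
linear,MV,H,0.952,FALSE
linear,MV,F,0.759,FALSE
linear,MV,SS,0.95,FALSE
linear,MV,ABC,0.957,FALSE
linear,MV,RI,0.967,FALSE
linear,MV,SC,0.96,FALSE
linear,MV,GA,0.956,FALSE
linear,MR,M1,0.766,FALSE
linear,MR,H,0.955,FALSE
linear,MR,SS,0.866,FALSE
linear,MR,ABC,0.864,FALSE
linear,MR,RI,0.934,FALSE
linear,MR,SC,0.928,FALSE
linear,MR,GA,0.915,FALSE
linear,HAC,M1,0.903,FALSE
linear,HAC,M2,0.868,FALSE
linear,HAC,H,0.901,FALSE
linear,HAC,F,0.78,FALSE
linear,HAC,SS,0.921,FALSE
linear,HAC,ABC,0.927,FALSE
linear,HAC,RI,0.923,FALSE
linear,HAC,SC,0.917,FALSE
linear,HAC,GA,0.916,FALSE
linear,HAC,HZ,0.824,FALSE
linear,CO,M1,0.893,FALSE
linear,CO,M2,0.84,FALSE
linear,CO,H,0.954,FALSE
linear,CO,F,0.728,FALSE
linear,CO,SS,0.939,FALSE
linear,CO,ABC,0.939,FALSE
linear,CO,RI,0.962,FALSE
linear,CO,SC,0.956,FALSE
linear,CO,GA,0.95,FALSE
linear,CO,HZ,0.783,FALSE
linear,EV,M1,0.949,FALSE
linear,EV,M2,0.955,FALSE
linear,EV,H,0.82,FALSE
linear,EV,F,0.915,FALSE
linear,EV,SS,0.916,FALSE
linear,EV,ABC,0.915,FALSE
linear,EV,RI,0.856,FALSE
linear,EV,SC,0.863,FALSE
linear,EV,GA,0.878,FALSE
linear,EV,HZ,0.938,FALSE
quadratic,BP,M1,0.809,FALSE
quadratic,BP,M2,0.808,FALSE
quadratic,BP,H,0.849,FALSE
quadratic,BP,F,0.816,FALSE
quadratic,BP,SS,0.819,FALSE
quadratic,BP,ABC,0.818,FALSE
quadratic,BP,RI,0.844,FALSE
quadratic,BP,SC,0.835,FALSE
quadratic,BP,GA,0.828,FALSE
quadratic,BP,HZ,0.812,FALSE
quadratic,MV,M1,0.923,FALSE
quadratic,MV,M2,0.859,FALSE
quadratic,MV,H,0.961,FALSE
quadratic,MV,F,0.789,FALSE
quadratic,MV,SS,0.954,FALSE
quadratic,MV,ABC,0.962,FALSE
quadratic,MV,RI,0.968,FALSE
quadratic,MV,SC,0.961,FALSE
quadratic,MV,GA,0.956,FALSE
quadratic,MV,HZ,0.817,FALSE
quadratic,MR,M1,0.789,FALSE
quadratic,MR,H,0.965,FALSE
quadratic,MR,SS,0.908,FALSE
quadratic,MR,ABC,0.912,FALSE
quadratic,MR,RI,0.955,FALSE
quadratic,MR,SC,0.952,FALSE
quadratic,MR,GA,0.944,FALSE
quadratic,MW,M1,0.861,TRUE
quadratic,MW,M2,0.826,FALSE
quadratic,MW,H,0.95,FALSE
quadratic,MW,F,0.808,FALSE
quadratic,MW,SS,0.908,FALSE
quadratic,MW,ABC,0.918,FALSE
quadratic,MW,RI,0.948,FALSE
quadratic,MW,SC,0.938,FALSE
quadratic,MW,GA,0.928,FALSE
quadratic,MW,HZ,0.815,FALSE
quadratic,HAC,M1,0.906,FALSE
quadratic,HAC,M2,0.883,FALSE
quadratic,HAC,H,0.957,FALSE
quadratic,HAC,F,0.841,FALSE
quadratic,HAC,SS,0.93,FALSE
quadratic,HAC,ABC,0.932,FALSE
quadratic,HAC,RI,0.956,FALSE
quadratic,HAC,SC,0.946,FALSE
quadratic,HAC,GA,0.939,FALSE
quadratic,HAC,HZ,0.859,FALSE
quadratic,CO,M1,0.904,FALSE
quadratic,CO,M2,0.84,FALSE
quadratic,CO,H,0.96,FALSE
quadratic,CO,F,0.759,FALSE
quadratic,CO,SS,0.944,FALSE
quadratic,CO,ABC,0.948,FALSE
quadratic,CO,RI,0.963,FALSE
quadratic,CO,SC,0.956,FALSE
quadratic,CO,GA,0.951,FALSE
quadratic,CO,HZ,0.792,FALSE
quadratic,EV,M1,0.954,FALSE
quadratic,EV,M2,0.958,FALSE
quadratic,EV,H,0.94,FALSE
quadratic,EV,F,0.929,FALSE
quadratic,EV,SS,0.947,FALSE
quadratic,EV,ABC,0.941,FALSE
quadratic,EV,RI,0.94,FALSE
quadratic,EV,SC,0.941,FALSE
quadratic,EV,GA,0.943,FALSE
quadratic,MP,H,0.76,FALSE
quadratic,MP,SS,0.743,FALSE
quadratic,MP,ABC,0.737,FALSE
quadratic,MP,RI,0.758,FALSE
quadratic,MP,SC,0.758,FALSE
quadratic,MP,GA,0.756,FALSE
logarithmic,BP,M1,0.777,FALSE
logarithmic,BP,M2,0.787,FALSE
logarithmic,BP,H,0.709,FALSE
logarithmic,BP,F,0.791,FALSE
logarithmic,BP,SS,0.752,FALSE
logarithmic,BP,ABC,0.761,FALSE
logarithmic,BP,RI,0.733,FALSE
logarithmic,BP,SC,0.73,FALSE
logarithmic,BP,GA,0.733,FALSE
logarithmic,BP,HZ,0.791,FALSE
logarithmic,MV,M1,0.852,FALSE
logarithmic,MV,M2,0.812,FALSE
logarithmic,MV,H,0.933,FALSE
logarithmic,MV,F,0.76,FALSE
logarithmic,MV,SS,0.887,FALSE
logarithmic,MV,ABC,0.893,FALSE
logarithmic,MV,RI,0.931,FALSE
logarithmic,MV,SC,0.919,FALSE
logarithmic,MV,GA,0.906,FALSE
logarithmic,MV,HZ,0.786,FALSE
logarithmic,MR,M1,0.7,TRUE
logarithmic,MR,H,0.868,FALSE
logarithmic,MR,SS,0.769,TRUE
logarithmic,MR,ABC,0.768,FALSE
logarithmic,MR,RI,0.845,TRUE
logarithmic,MR,SC,0.831,TRUE
logarithmic,MR,GA,0.812,TRUE
logarithmic,MW,M1,0.8647,TRUE
logarithmic,MW,M2,0.804,FALSE
logarithmic,MW,H,0.942,FALSE
logarithmic,MW,F,0.744,FALSE
logarithmic,MW,SS,0.888,FALSE
logarithmic,MW,ABC,0.894,FALSE
logarithmic,MW,RI,0.937,FALSE
logarithmic,MW,SC,0.925,FALSE
logarithmic,MW,GA,0.912,FALSE
logarithmic,MW,HZ,0.774,FALSE
logarithmic,HAC,M1,0.891,FALSE
logarithmic,HAC,M2,0.869,FALSE
logarithmic,HAC,H,0.948,FALSE
logarithmic,HAC,F,0.814,FALSE
logarithmic,HAC,SS,0.918,FALSE
logarithmic,HAC,ABC,0.918,FALSE
logarithmic,HAC,RI,0.949,FALSE
logarithmic,HAC,SC,0.939,FALSE
logarithmic,HAC,GA,0.931,FALSE
logarithmic,HAC,HZ,0.842,FALSE
logarithmic,CO,M1,0.83,FALSE
logarithmic,CO,M2,0.797,FALSE
logarithmic,CO,H,0.928,FALSE
logarithmic,CO,F,0.731,FALSE
logarithmic,CO,SS,0.871,FALSE
logarithmic,CO,ABC,0.87,FALSE
logarithmic,CO,RI,0.921,FALSE
logarithmic,CO,SC,0.908,FALSE
logarithmic,CO,GA,0.894,FALSE
logarithmic,CO,HZ,0.764,FALSE
logarithmic,EV,M1,0.947,FALSE
logarithmic,EV,M2,0.947,FALSE
logarithmic,EV,H,0.913,FALSE
logarithmic,EV,F,0.924,FALSE
logarithmic,EV,SS,0.943,FALSE
logarithmic,EV,ABC,0.937,FALSE
logarithmic,EV,RI,0.924,FALSE
logarithmic,EV,SC,0.927,FALSE
logarithmic,EV,GA,0.933,FALSE
logarithmic,EV,HZ,0.937,FALSE
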