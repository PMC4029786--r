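genotype,sample,gamma,A0,Aa,gamma_lo,gamma_hi,A0_lo,A0_hi,Aa_lo,Aa_hi,retained
cfq,1,0.03711,129.9,17440,0.0334,0.04081,93.55,166.3,12780,22100,FALSE
cfq,2,0.04296,127.2,24850,0.03984,0.04607,95.37,159.1,21300,28390,TRUE
cfq,3,0.04128,167.3,22590,0.03916,0.04340,139.9,194.7,20540,24650,TRUE
WT,1,0.03823,210.1,53640,0.03502,0.04144,156.2,263.9,35500,71770,TRUE
WT,2,0.05020,127.5,38570,0.04835,0.05205,107.7,147.3,36640,40500,FALSE
WT,3,0.03907,304.8,66060,0.03656,0.04159,243.8,365.9,52480,79640,TRUE
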