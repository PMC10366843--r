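segment,m1_correct,m1_incorrect,m2_correct,m2_incorrect,m3_correct,m3_incorrect,undetected
AComm,19,25,44,0,36,8,16
R-A1,51,9,60,0,60,0,0
L-A1,49,10,59,0,59,0,1
R-M1,55,5,60,0,60,0,0
L-M1,58,2,60,0,59,1,0
R-ICA,51,9,50,10,50,10,0
L-ICA,51,9,52,8,52,8,0
R-PComm,8,6,14,0,14,0,46
L-PComm,10,8,18,0,18,0,42
R-P1,52,8,57,3,58,2,0
L-P1,51,9,60,0,60,0,0
R-P2,55,5,60,0,60,0,0
L-P2,51,9,60,0,60,0,0
BA,53,7,60,0,60,0,0
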