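compound,n_experiments,tested_concentrations_uM,clinical_finding_code,assay_positive_max,amplitude_positive_therapeutic,tiq_positive_therapeutic,outcome_max_dose,outcome_therapeutic_dose
B,8,0.3;3;30,NE,TRUE,TRUE,TRUE,FP,FP
C,6,0.003;0.03;0.3,C,TRUE,FALSE,TRUE,TP,TP
D,6,0.3;3;30,NE,TRUE,FALSE,FALSE,FP,TN
E,6,0.3;3;30,NE,TRUE,FALSE,TRUE,FP,FP
F,6,0.3;3;30,D,TRUE,TRUE,TRUE,TP,TP
G,7,0.3;3;30,D,FALSE,FALSE,FALSE,FN,FN
H,7,0.3;3;30,D,TRUE,FALSE,TRUE,TP,TP
I,7,0.3;3;30,D,FALSE,FALSE,FALSE,FN,FN
J,6,0.03;0.3;3,NE,TRUE,FALSE,TRUE,FP,FP
M,6,0.3;3;30,D,TRUE,FALSE,FALSE,TP,FN
N,6,0.3;3;30,NE,TRUE,FALSE,FALSE,FP,TN
R,6,0.3;3;30,NE,FALSE,FALSE,FALSE,TN,TN
S,4,0.3;3;30,NE,TRUE,FALSE,FALSE,FP,TN
T,6,0.3;3;30,D,TRUE,TRUE,FALSE,TP,TP
Z,6,0.3;3;30,D,TRUE,FALSE,TRUE,TP,TP
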