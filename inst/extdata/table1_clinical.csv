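compound,clinical_finding,pct_subjects_affected,min_free_exposure_uM,max_free_exposure_uM,exposure_is_total
B,none,0,0.0024,0.6597,FALSE
C,constipation,17,0.0010,0.0029,FALSE
D,none,0,0.0050,0.0352,FALSE
E,none,0,0.0060,2.6331,FALSE
F,diarrhea,67,0.00007,0.6051,FALSE
G,diarrhea,53,6,12,TRUE
H,diarrhea,17,0.0006,0.0710,FALSE
I,loose_stools,25,0.7,18.9,TRUE
J,none,0,0.000008,0.0008,FALSE
M,diarrhea,17,0.0017,0.0506,FALSE
N,none,0,0.00014,0.0373,TRUE
R,none,0,0.000009,0.0837,FALSE
S,nausea,13,0.000125,0.001,FALSE
T,diarrhea,67,0.00935,0.1837,FALSE
Z,loose_stools,100,0.00027,2,FALSE
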