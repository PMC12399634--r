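policy_id,stage,year,X1,X2,X3,X4,X5,X6,X7,X8,X9
P1,Initiation,1995,1,0.33,0.8,0.67,0.4,0.88,0.2,0.25,0.71
P2,Initiation,1995,0.5,0.67,0.8,0.43,0.4,0.63,0.4,0.25,0.86
P3,Initiation,1995,0.33,1,0.4,0.57,0.4,0.14,0.6,0.25,0.43
P4,Initiation,2000,1,1,1,0.71,0.6,0.71,0.6,0.25,0.86
P5,Expansion,2001,0.5,1,0.8,0.43,0.6,1,0.4,0.25,0.43
P6,Expansion,2006,0.83,1,0.8,0.86,0.8,0.83,0.8,0.25,0.86
P7,Expansion,2009,0.5,1,0.8,0.71,0.8,1,0.6,0.25,0.71
P8,Expansion,2011,0.5,0.67,1,0.71,0.4,0.86,0.6,0.25,0.86
P9,Improvement,2016,0.83,0.67,1,0.86,1,1,1,0.25,1
P10,Improvement,2019,0.67,1,0.8,0.86,0.6,0.5,0.8,0.25,0.86
P11,Improvement,2021,0.67,0.67,1,0.86,0.4,0.63,0.6,0.25,0.57
P12,Improvement,2022,0.67,1,1,1,1,0.75,0.8,0.25,1
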