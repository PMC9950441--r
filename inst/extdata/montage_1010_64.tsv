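channel	x	y	scalp
Fp1	-0.108	0.9	1
FPz	0	0.9	1
Fp2	0.108	0.9	1
AF7	-0.642	0.72	1
AF3	-0.321	0.72	1
AFz	0	0.72	1
AF4	0.321	0.72	1
AF8	0.642	0.72	1
F7	-0.766	0.54	1
F5	-0.575	0.54	1
F3	-0.383	0.54	1
F1	-0.192	0.54	1
Fz	0	0.54	1
F2	0.192	0.54	1
F4	0.383	0.54	1
F6	0.575	0.54	1
F8	0.766	0.54	1
FT7	-0.93	0.31	1
FC5	-0.652	0.27	1
FC3	-0.435	0.27	1
FC1	-0.217	0.27	1
FCz	0	0.27	1
FC2	0.217	0.27	1
FC4	0.435	0.27	1
FC6	0.652	0.27	1
FT8	0.93	0.31	1
T7	-1	0	1
C5	-0.676	0	1
C3	-0.451	0	1
C1	-0.225	0	1
Cz	0	0	1
C2	0.225	0	1
C4	0.451	0	1
C6	0.676	0	1
T8	1	0	1
TP7	-0.93	-0.31	1
CP5	-0.652	-0.27	1
CP3	-0.435	-0.27	1
CP1	-0.217	-0.27	1
CPz	0	-0.27	1
CP2	0.217	-0.27	1
CP4	0.435	-0.27	1
CP6	0.652	-0.27	1
TP8	0.93	-0.31	1
P9	-0.888	-0.62	1
P7	-0.766	-0.54	1
P5	-0.575	-0.54	1
P3	-0.383	-0.54	1
P1	-0.192	-0.54	1
Pz	0	-0.54	1
P2	0.192	-0.54	1
P4	0.383	-0.54	1
P6	0.575	-0.54	1
P8	0.766	-0.54	1
P10	0.888	-0.62	1
PO7	-0.642	-0.72	1
PO3	-0.321	-0.72	1
POz	0	-0.72	1
PO4	0.321	-0.72	1
PO8	0.642	-0.72	1
O1	-0.108	-0.9	1
Oz	0	-0.9	1
O2	0.108	-0.9	1
Iz	0	-1	1
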