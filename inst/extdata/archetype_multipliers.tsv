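gene	alps_like	ebv_like	hd_like
SLC2A1	1	1	0.015
HK1	4	4	4
GCK	0	4	0
PKM	4	4	0
LDHA	4	4	0
SLC16A1	1	0.02	0
G6PD	0.01	1	4
PGD	0.01	0.06	4
RPIA	0.01	1	4
TKT	0.01	4	4
SLC2A2	0.02	4	0.3
RBKS	0.02	4	0.3
MPC1	1	1	0
PDHA1	1	1	0
CS	4	1	1
NDUFS1	1	0.2	1
MDH1	4	4	1
SLC25A4	1	0.2	1
SLC25A3	1	0.2	1
SLC1A5	4	0.3	0
SLC25A22	4	0.3	0
GLS	4	0.3	0
GLUD1	1	0.3	0
OGDH	1	0.3	0
SLC25A18	1	0.3	0
GOT1	4	0	0
SLC7A5	0	1	1
EEF2	4	1	0.005
CD36	1	1	1
ACSL1	1	1	1
FASN	0.5	0.5	0.5
SLC25A1	0.5	0.5	0.5
CPT1A	0	0.5	4
ACADVL	0	0.5	4
GSS	0.03	4	0.5
GPX1	0.03	4	0.5
GSR	0.03	4	0.5
GSTO1	0	1	0.5
ABCC1	0.03	1	0.5
SOD2	0	1	4
SOD1	0	1	4
CAT	0.5	1	1
SLC23A1	0	1	4
GLRX	0	1	4
CYBB	0	0	0
SLC48A1	1	0.2	0.02
SLC7A11	0.03	4	0.5
HMOX1	4	0	0
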