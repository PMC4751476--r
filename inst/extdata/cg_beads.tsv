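resid	radius	eps	charge
BB	2.3	0.20	0
ALA	2.3	0.20	0
ARG	3.4	0.20	1
ASN	2.9	0.20	0
ASP	2.8	0.20	-1
CYS	2.7	0.20	0
GLN	3.1	0.20	0
GLU	3.0	0.20	-1
GLY	2.3	0.20	0
HIS	3.1	0.20	0
ILE	3.1	0.25	0
LEU	3.1	0.25	0
MET	3.2	0.25	0
PHE	3.4	0.25	0
PRO	2.8	0.20	0
SER	2.5	0.20	0
THR	2.7	0.20	0
TRP	3.6	0.25	0
TYR	3.5	0.25	0
VAL	2.9	0.25	0
LYS	3.2	0.20	1
UNK	2.8	0.20	0
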